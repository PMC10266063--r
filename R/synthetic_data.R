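#' Synthetic slab density profile with known ground truth
#'
#' Evaluates the tanh interface profile on bin centers, optionally
#' mirrored into a two-interface slab, and adds noise.  The exact inverse
#' of [fit_tanh()]: zero-noise profiles are recovered to solver tolerance.
#'
#' @param c1,c2 Dilute and dense concentrations, beads/nm^3 (`c2 > c1`).
#' @param x0 Interface midpoint, nm (for the two-interface slab, the left
#'   midpoint; the right one is mirrored about Lx/2).
#' @param L Interface width, nm (warned if >= Lx/4).
#' @param lx Profile support length, nm.
#' @param box_yz Transverse box lengths, nm (bookkeeping only).
#' @param bin_width Bin width, nm.
#' @param noise Multiplicative Gaussian noise fraction.
#' @param noise_additive Additive Gaussian noise sd, beads/nm^3.
#' @param two_interface Mirror into a slab with two interfaces.
#' @param seed Integer seed.
#' @return List with `profile` (a `density_profile`) and `truth`.
#' @export
gen_tanh_profile <- function(c1 = 0.1, c2 = 5, x0 = 60, L = 8, lx = 250,
                             box_yz = c(30, 30), bin_width = 1, noise = 0,
                             noise_additive = 0, two_interface = FALSE,
                             seed = 1) {
  if (c2 <= c1 || c1 < 0) stop("need c2 > c1 >= 0")
  if (L <= 0) stop("L must be positive")
  if (L >= lx / 4)
    warning("interface width L >= Lx/4: geometry leaves no bulk plateaus")
  n_bins <- round(lx / bin_width)
  x <- (seq_len(n_bins) - 0.5) * (lx / n_bins)
  if (two_interface) {
    x0r <- lx - x0
    y <- c1 + 0.5 * (c2 - c1) *
      (tanh(2 * (x - x0) / L) - tanh(2 * (x - x0r) / L))
  } else {
    y <- tanh_profile_fn(x, c1, c2, x0, L)
  }
  if (noise > 0 || noise_additive > 0) {
    y <- with_seed(seed, {
      out <- y * (1 + noise * rnorm(length(y)))
      out + noise_additive * rnorm(length(y))
    })
    y <- pmax(y, 0)
  }
  list(profile = as_density_profile(x, y, c(lx, box_yz)),
       truth = list(c1 = c1, c2 = c2, x0 = x0, L = L, xi = L / 4,
                    two_interface = two_interface))
}

#' Synthetic gamma(T) table obeying the critical power law
#'
#' Draws surface tensions from `gamma0 * tau^mu` with multiplicative noise
#' and `n_repeats` pseudo-repeats per temperature (mirroring independent
#' simulation repeats), reporting per-point means and SEMs.  An optional
#' crossover imposes a fractional deviation from the power law above
#' `crossover_tau`, emulating the end of the critical regime.
#'
#' @param tc Critical temperature, K.
#' @param gamma0 Critical amplitude (any unit).
#' @param t_grid Temperatures, K (all below `tc`).
#' @param noise Multiplicative noise fraction per pseudo-repeat.
#' @param n_repeats Pseudo-repeats per temperature.
#' @param seed Integer seed.
#' @param crossover_tau Optional tau above which the power law breaks.
#' @param deviation Fractional deviation imposed above the crossover.
#' @param mu Surface-tension exponent.
#' @return List with `table` (`temperature`, `gamma`, `sem`) and `truth`.
#' @export
gen_powerlaw_gamma <- function(tc = 320, gamma0 = 2,
                               t_grid = seq(240, 305, by = 5),
                               noise = 0.05, n_repeats = 5, seed = 1,
                               crossover_tau = NULL, deviation = 0,
                               mu = ising_constants()$mu) {
  if (any(t_grid >= tc)) stop("all temperatures must lie below Tc")
  tau <- 1 - t_grid / tc
  g_true <- gamma0 * tau^mu
  if (!is.null(crossover_tau))
    g_true <- g_true * ifelse(tau > crossover_tau, 1 + deviation, 1)
  tab <- with_seed(seed, {
    reps <- vapply(g_true, function(g)
      g * (1 + noise * rnorm(n_repeats)), numeric(n_repeats))
    if (n_repeats == 1) reps <- matrix(reps, nrow = 1)
    data.frame(temperature = t_grid,
               gamma = colMeans(reps),
               sem = if (n_repeats > 1 && noise > 0)
                 apply(reps, 2, stats::sd) / sqrt(n_repeats)
               else rep(0, length(t_grid)))
  })
  list(table = tab,
       truth = list(tc = tc, gamma0 = gamma0, mu = mu, noise = noise,
                    crossover_tau = crossover_tau, deviation = deviation))
}

#' Synthetic pressure-tensor series with prescribed anisotropy
#'
#' AR(1) series for the anisotropy `px - (py + pz)/2` with prescribed
#' stationary mean, standard deviation, and autocorrelation time (in
#' samples); `py = pz` are held at a constant baseline.  The analytic
#' surface tension is `(Lx/2) * mean`, with the AR(1) standard error of
#' the mean as truth for SEM validation.
#'
#' @param mean_anisotropy Stationary mean of the anisotropy, kB*T0/nm^3.
#' @param ac_time Autocorrelation time in sample strides.
#' @param sigma Stationary standard deviation.
#' @param n Number of samples (should exceed ~10 * `ac_time`).
#' @param lx Box length along x, nm.
#' @param p0 Baseline isotropic pressure.
#' @param seed Integer seed.
#' @return List with `samples` (`time_ns`, `px`, `py`, `pz`) and `truth`
#'   (`gamma`, `sem_gamma`, plus the generator parameters).
#' @export
gen_pressure_series <- function(mean_anisotropy = 1e-3, ac_time = 5,
                                sigma = 0.01, n = 1000, lx = 250,
                                p0 = 0.1, seed = 1) {
  if (n <= 10 * ac_time)
    warning("series shorter than 10 autocorrelation times")
  phi <- exp(-1 / ac_time)
  a <- with_seed(seed, {
    eps <- rnorm(n)
    out <- numeric(n)
    out[1] <- mean_anisotropy + sigma * eps[1]
    innov_sd <- sigma * sqrt(1 - phi^2)
    for (t in 2:n)
      out[t] <- mean_anisotropy + phi * (out[t - 1] - mean_anisotropy) +
        innov_sd * eps[t]
    out
  })
  sem_mean <- sigma * sqrt((1 + phi) / ((1 - phi) * n))
  samples <- data.frame(time_ns = seq_len(n), px = p0 + a, py = p0,
                        pz = p0)
  list(samples = samples,
       truth = list(gamma = lx / 2 * mean_anisotropy,
                    sem_gamma = lx / 2 * sem_mean, phi = phi,
                    mean_anisotropy = mean_anisotropy, sigma = sigma,
                    lx = lx))
}

#' Synthetic trajectory with an imposed Ornstein-Zernike density spectrum
#'
#' Builds a periodic 1-D Gaussian random field with spectrum
#' `S(k) = S0 / (1 + k^2 xi^2)`, modulates a Poisson bead density with it,
#' and scatters beads accordingly; transverse coordinates are uniform.
#' The ground-truth correlation length is `xi`.  With `xi = 0` the field
#' is white noise and the estimator should return ~0.
#'
#' @param xi Imposed correlation length, nm.
#' @param width Field support along x, nm.
#' @param bin_width Field grid spacing, nm.
#' @param mean_count Mean beads per grid cell per frame.
#' @param amp Relative field amplitude (sd of the density modulation).
#' @param n_frames Number of frames.
#' @param box_yz Transverse box lengths, nm.
#' @param seed Integer seed.
#' @return List with `trajectory` (frames of bead positions on
#'   `[0, width)` in x) and `truth`.
#' @export
gen_oz_field <- function(xi = 3, width = 64, bin_width = 1,
                         mean_count = 100, amp = 0.5, n_frames = 200,
                         box_yz = c(15, 15), seed = 1) {
  n_bins <- round(width / bin_width)
  k <- 2 * pi * c(0, seq_len(n_bins %/% 2), -rev(seq_len((n_bins - 1) %/% 2))) /
    width
  Sk <- 1 / (1 + k^2 * xi^2)
  Sk[1] <- 0  # no mean shift
  frames <- with_seed(seed, lapply(seq_len(n_frames), function(f) {
    z <- complex(real = rnorm(n_bins), imaginary = rnorm(n_bins))
    field <- Re(fft(z * sqrt(Sk), inverse = TRUE)) / n_bins
    s <- stats::sd(field)
    if (s > 0) field <- field / s * amp
    lambda <- pmax(mean_count * (1 + field), 0)
    counts <- stats::rpois(n_bins, lambda)
    xs <- rep((seq_len(n_bins) - 1) * bin_width, counts) +
      runif(sum(counts), 0, bin_width)
    cbind(xs, runif(length(xs), 0, box_yz[1]),
          runif(length(xs), 0, box_yz[2]))
  }))
  nb <- vapply(frames, nrow, integer(1))
  topo <- list(types = rep(1L, max(nb)), bonds = matrix(integer(0), 0, 2),
               chain = rep(1L, max(nb)), n_beads = max(nb))
  traj <- structure(list(frames = frames, times = seq_len(n_frames),
                         box = c(width, box_yz), topology = topo,
                         temperature = NA_real_),
                    class = "trajectory")
  list(trajectory = traj, truth = list(xi = xi, amp = amp,
                                       mean_count = mean_count))
}

#' Toy chain trajectories with closed-form radius of gyration
#'
#' Fixtures for the Rg estimator: a straight rod of equally spaced beads
#' (`Rg = spacing * sqrt((n^2 - 1)/12)`), all-coincident beads (`Rg = 0`),
#' or uniform ideal-gas beads.
#'
#' @param kind "rod", "point", or "uniform".
#' @param n_beads Beads per chain.
#' @param spacing Bead spacing for the rod, nm.
#' @param box Box lengths, nm.
#' @param n_frames Number of identical (rod/point) or independent
#'   (uniform) frames.
#' @param seed Integer seed (uniform only).
#' @return List with `trajectory` and `truth` (`rg` where closed-form).
#' @export
gen_toy_trajectory <- function(kind = c("rod", "point", "uniform"),
                               n_beads = 24, spacing = 1,
                               box = c(100, 30, 30), n_frames = 1,
                               seed = 1) {
  kind <- match.arg(kind)
  base <- switch(kind,
    rod = cbind(seq_len(n_beads) * spacing + box[1] / 4,
                rep(box[2] / 2, n_beads), rep(box[3] / 2, n_beads)),
    point = matrix(rep(box / 2, each = n_beads), n_beads, 3),
    uniform = NULL)
  frames <- if (kind == "uniform") {
    with_seed(seed, lapply(seq_len(n_frames), function(f)
      cbind(runif(n_beads, 0, box[1]), runif(n_beads, 0, box[2]),
            runif(n_beads, 0, box[3]))))
  } else {
    rep(list(base), n_frames)
  }
  n_chain_beads <- if (kind == "uniform") 1L else n_beads
  topo <- if (kind == "uniform") {
    list(types = rep(1L, n_beads), bonds = matrix(integer(0), 0, 2),
         chain = seq_len(n_beads), n_beads = n_beads)
  } else {
    build_topology(polymer_spec(1, 2), 1)  # placeholder, fixed below
  }
  if (kind != "uniform") {
    i1 <- seq_len(n_beads - 1L)
    topo <- list(types = rep(c(1L, 2L), length.out = n_beads),
                 bonds = cbind(i1, i1 + 1L), chain = rep(1L, n_beads),
                 n_beads = n_beads)
  }
  traj <- structure(list(frames = frames, times = seq_len(n_frames),
                         box = box, topology = topo,
                         temperature = NA_real_),
                    class = "trajectory")
  truth <- switch(kind,
    rod = list(rg = spacing * sqrt((n_beads^2 - 1) / 12)),
    point = list(rg = 0),
    uniform = list())
  list(trajectory = traj, truth = truth)
}
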