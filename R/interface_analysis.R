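#' Convert surface tension between simulation and SI units
#'
#' Internal surface-tension unit is kB*T0/nm^2; with T0 = 300 K,
#' 1 kB*T0/nm^2 = kB * 300 / 1e-18 N/m.
#'
#' @param gamma Value(s) in kB*T0/nm^2.
#' @param t0 Reference temperature, K.
#' @return N/m.
#' @export
gamma_to_si <- function(gamma, t0 = 300) gamma * KB_SI * t0 / 1e-18

#' @rdname gamma_to_si
#' @param gamma_si Value(s) in N/m.
#' @export
gamma_from_si <- function(gamma_si, t0 = 300) gamma_si * 1e-18 / (KB_SI * t0)

# SEM of a (possibly autocorrelated) series by non-overlapping block means.
block_sem <- function(x, n_blocks = 10) {
  n <- length(x)
  n_blocks <- max(2L, min(n_blocks, n %/% 2))
  if (n < 4) return(stats::sd(x) / sqrt(max(n, 1)))
  size <- n %/% n_blocks
  means <- vapply(seq_len(n_blocks), function(b)
    mean(x[((b - 1) * size + 1):(b * size)]), numeric(1))
  stats::sd(means) / sqrt(n_blocks)
}

#' Surface tension via the Kirkwood-Buff route
#'
#' Computes the interfacial tension of a slab with two interfaces normal
#' to x from the time-averaged pressure-tensor anisotropy,
#' `gamma = (Lx/2) * <px - (py + pz)/2>`.  The factor 1/2 accounts for the
#' two interfaces of the periodic slab geometry; a single-interface
#' geometry must not use this estimator unmodified.
#'
#' @param samples A data.frame with columns `px`, `py`, `pz` (kB*T0/nm^3),
#'   or a list of such data.frames, one per independent repeat.
#' @param lx Box length along the slab normal, nm.
#' @param temperature Temperature label, K (carried through).
#' @param t0 Reference temperature for unit conversion, K.
#' @return Object of class `surface_tension_estimate` with `gamma` and
#'   `sem` in kB*T0/nm^2, `gamma_si` and `sem_si` in N/m, and `n_repeats`.
#'   With a single repeat the SEM comes from block averaging of the time
#'   series; with several repeats it is the SEM across repeat means.
#' @export
kirkwood_buff_gamma <- function(samples, lx, temperature = NA_real_,
                                t0 = 300) {
  if (is.data.frame(samples)) samples <- list(samples)
  if (!length(samples)) stop("no pressure samples")
  for (s in samples) {
    if (!all(c("px", "py", "pz") %in% names(s)))
      stop("pressure samples need columns px, py, pz")
    if (nrow(s) < 2) stop("need at least 2 pressure samples")
  }
  aniso <- lapply(samples, function(s) s$px - 0.5 * (s$py + s$pz))
  per_rep <- vapply(aniso, function(a) (lx / 2) * mean(a), numeric(1))
  gamma <- mean(per_rep)
  if (length(per_rep) > 1) {
    sem <- stats::sd(per_rep) / sqrt(length(per_rep))
  } else {
    sem <- (lx / 2) * block_sem(aniso[[1]])
  }
  structure(list(temperature = temperature, gamma = gamma, sem = sem,
                 gamma_si = gamma_to_si(gamma, t0),
                 sem_si = gamma_to_si(sem, t0),
                 n_repeats = length(per_rep), lx = lx, t0 = t0),
            class = "surface_tension_estimate")
}

#' @export
print.surface_tension_estimate <- function(x, ...) {
  cat(sprintf(
    "Surface tension (Kirkwood-Buff, %d repeat%s)%s:\n",
    x$n_repeats, if (x$n_repeats > 1) "s" else "",
    if (is.na(x$temperature)) "" else sprintf(" at T = %g K", x$temperature)))
  cat(sprintf("  gamma = %.4g +- %.2g kB*T0/nm^2  (%.4g +- %.2g N/m)\n",
              x$gamma, x$sem, x$gamma_si, x$sem_si))
  invisible(x)
}

# Periodic (circular) mean of coordinates on [0, L).
periodic_mean <- function(x, L) {
  th <- x / L * 2 * pi
  m <- atan2(mean(sin(th)), mean(cos(th)))
  (m %% (2 * pi)) / (2 * pi) * L
}

#' Bead number-density profile along the slab normal
#'
#' Bins bead x positions frame by frame.  By default each frame is first
#' recentered so the periodic center of mass of the beads sits at Lx/2,
#' which keeps a slowly drifting slab from smearing the interfaces.
#' Bead count is conserved exactly: `sum(c) * bin_width * Ly * Lz` equals
#' the bead count.
#'
#' @param traj A `trajectory`.
#' @param bin_width Bin width along x, nm (default 1, the bead diameter).
#' @param recenter Recenter each frame's dense slab at Lx/2.
#' @return Object of class `density_profile`: data.frame with `x` (bin
#'   centers, nm) and `c` (beads/nm^3), with attributes `bin_width`,
#'   `box`, `n_frames`, `n_beads`.
#' @export
bin_profile <- function(traj, bin_width = 1, recenter = TRUE) {
  if (!length(traj$frames)) stop("empty trajectory")
  Lx <- traj$box[1]
  n_bins <- max(2L, round(Lx / bin_width))
  bw <- Lx / n_bins
  breaks <- seq(0, Lx, length.out = n_bins + 1)
  counts <- numeric(n_bins)
  for (fr in traj$frames) {
    x <- fr[, 1] %% Lx
    if (recenter) {
      cm <- periodic_mean(x, Lx)
      x <- (x - cm + Lx / 2) %% Lx
    }
    idx <- pmin(floor(x / bw) + 1L, n_bins)
    counts <- counts + tabulate(idx, nbins = n_bins)
  }
  nf <- length(traj$frames)
  area <- traj$box[2] * traj$box[3]
  conc <- counts / (nf * bw * area)
  out <- data.frame(x = (breaks[-1] + breaks[-length(breaks)]) / 2, c = conc)
  structure(out, class = c("density_profile", "data.frame"),
            bin_width = bw, box = traj$box, n_frames = nf,
            n_beads = nrow(traj$frames[[1]]))
}

#' Construct a density profile from bare vectors
#' @param x Bin centers, nm.
#' @param c Concentration, beads/nm^3.
#' @param box Box dimensions, nm.
#' @param n_frames Frames averaged.
#' @keywords internal
#' @export
as_density_profile <- function(x, c, box, n_frames = 1) {
  bw <- if (length(x) > 1) x[2] - x[1] else box[1]
  structure(data.frame(x = x, c = c),
            class = c("density_profile", "data.frame"),
            bin_width = bw, box = box, n_frames = n_frames,
            n_beads = sum(c) * bw * box[2] * box[3] / n_frames)
}

tanh_profile_fn <- function(x, c1, c2, x0, L) {
  0.5 * (c1 + c2) + 0.5 * (c2 - c1) * tanh(2 * (x - x0) / L)
}

fit_half_tanh <- function(x, y, rising) {
  if (!rising) x <- -x
  c2s <- max(y)
  # keep the start away from 0: nls gradients use relative steps, and a
  # ~0 start for the (linear) dilute level yields a degenerate column
  c1s <- max(min(y), 1e-3 * c2s)
  # starts from level crossings scanned in order (robust to plateau noise)
  ord <- order(x)
  xo <- x[ord]
  yo <- y[ord]
  cross <- function(level) {
    i <- which(yo >= level)[1]
    if (is.na(i)) xo[length(xo)] else xo[i]
  }
  x0s <- cross((c1s + c2s) / 2)
  Ls <- max(cross(c1s + 0.75 * (c2s - c1s)) -
              cross(c1s + 0.25 * (c2s - c1s)),
            diff(range(x)) / 100)
  dat <- data.frame(x = x, y = y)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ tanh_profile_fn(x, c1, c2, x0, L), data = dat,
      start = list(c1 = c1s, c2 = c2s, x0 = x0s, L = Ls),
      lower = c(0, 0, min(x), 1e-6),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e)
      stop("tanh interface fit failed (non-sigmoidal profile?): ",
           conditionMessage(e)))
  est <- coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, 4))
  x0 <- if (rising) est[["x0"]] else -est[["x0"]]
  list(c1 = est[["c1"]], c2 = est[["c2"]], x0 = x0, L = est[["L"]],
       se = se, sigma = summary(fit)$sigma, fit = fit)
}

#' Fit tanh interface profiles to a slab density profile
#'
#' Fits `c(x) = (c1 + c2)/2 + (c2 - c1)/2 * tanh(2 (x - x0) / L)` to each
#' of the two interfaces of a recentered slab profile independently (the
#' right interface is mirrored before fitting), then averages the width.
#' `c1` and `c2` are the dilute and dense phase concentrations, `x0` the
#' interface midpoint and `L` the interface width.
#'
#' @param profile A `density_profile` (or anything with `x` and `c`
#'   columns plus a `box` attribute).
#' @param min_contrast Minimum dense/dilute ratio for the profile to count
#'   as sigmoidal.
#' @return Object of class `interface_fit` with components `c1`, `c2`,
#'   `L`, `x0` (length 2: left and right midpoints), standard errors, the
#'   per-interface sub-fits, and the input profile.  Supports `print()`,
#'   `summary()`, `coef()`, `predict()` and `plot()`.
#' @export
fit_tanh <- function(profile, min_contrast = 2) {
  x <- profile$x
  y <- profile$c
  box <- attr(profile, "box")
  Lx <- if (!is.null(box)) box[1] else max(x) + (x[2] - x[1]) / 2
  if (max(y) <= 0 || max(y) / max(min(y), 1e-12) < min_contrast)
    stop("profile lacks distinct dense and dilute plateaus ",
         "(max/min ratio < ", min_contrast, "): cannot fit an interface")
  center <- Lx / 2
  left <- x <= center
  fl <- fit_half_tanh(x[left], y[left], rising = TRUE)
  fr <- fit_half_tanh(x[!left], y[!left], rising = FALSE)
  L <- mean(c(fl$L, fr$L))
  se_comb <- function(name) {
    s <- c(fl$se[[name]], fr$se[[name]])
    if (all(is.na(s))) NA_real_ else sqrt(sum(s^2, na.rm = TRUE)) / 2
  }
  out <- structure(list(
    c1 = mean(c(fl$c1, fr$c1)), c2 = mean(c(fl$c2, fr$c2)),
    x0 = c(left = fl$x0, right = fr$x0), L = L,
    se = c(c1 = se_comb("c1"), c2 = se_comb("c2"), L = se_comb("L")),
    sigma = mean(c(fl$sigma, fr$sigma)),
    halves = list(left = fl, right = fr),
    profile = profile, lx = Lx), class = "interface_fit")
  if (L > Lx / 4)
    warning("interface width L = ", signif(L, 3), " nm is comparable to ",
            "the box (Lx = ", Lx, " nm): finite-size effects likely")
  out
}

#' @export
print.interface_fit <- function(x, ...) {
  cat("Interface fit (tanh profile, two interfaces averaged):\n")
  cat(sprintf("  c1 (dilute) = %.4g, c2 (dense) = %.4g beads/nm^3\n",
              x$c1, x$c2))
  cat(sprintf("  width L = %.4g +- %.2g nm  (xi = L/4 = %.4g nm)\n",
              x$L, x$se[["L"]], x$L / 4))
  cat(sprintf("  midpoints x0 = %.4g, %.4g nm\n", x$x0[1], x$x0[2]))
  invisible(x)
}

#' @export
coef.interface_fit <- function(object, ...) {
  c(c1 = object$c1, c2 = object$c2, L = object$L,
    x0_left = unname(object$x0[1]), x0_right = unname(object$x0[2]))
}

#' @export
summary.interface_fit <- function(object, ...) {
  print(object)
  cat(sprintf("  residual sd = %.3g; xi = %.4g nm\n",
              object$sigma, object$L / 4))
  invisible(object)
}

#' @export
predict.interface_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$profile$x else
    if (is.data.frame(newdata)) newdata$x else newdata
  center <- object$lx / 2
  hl <- object$halves$left
  hr <- object$halves$right
  ifelse(x <= center,
         tanh_profile_fn(x, hl$c1, hl$c2, hl$x0, hl$L),
         tanh_profile_fn(-x, hr$c1, hr$c2, -hr$x0, hr$L))
}

#' @export
plot.interface_fit <- function(x, ...) {
  graphics::plot(x$profile$x, x$profile$c, pch = 16, cex = 0.6,
                 xlab = "x (nm)", ylab = "c (beads/nm^3)",
                 main = "Slab density profile and tanh interface fit", ...)
  xs <- seq(min(x$profile$x), max(x$profile$x), length.out = 400)
  graphics::lines(xs, predict(x, xs), col = "red", lwd = 2)
  invisible(x)
}

#' Correlation length from the interface width
#'
#' The tanh interface profile decays to its bulk plateaus as
#' exp(-4 x / L), so the Ornstein-Zernike correlation length is
#' `xi = L / 4`.
#'
#' @param L Interface width(s), nm (> 0).
#' @return Correlation length, nm.
#' @export
xi_from_width <- function(L) {
  if (any(L < 0)) stop("interface width must be positive")
  L / 4
}

#' Decay length of the far-field concentration tail
#'
#' Fits `c(x) - c1 ~ exp(x / xi)` on the dilute side of the left
#' interface, at distances beyond `min_dist` widths from the midpoint,
#' by linear regression of `log(c - c1)` on `x`.  For an ideal tanh
#' profile the result is L/4 (the interface-width/correlation-length
#' relation), independent of the other profile parameters.
#'
#' @param profile A `density_profile` covering the dilute tail.
#' @param fit Optional `interface_fit`; fitted on the fly if missing.
#' @param min_dist,max_dist Window on the dilute side, in units of L,
#'   measured from the interface midpoint.
#' @return List with `xi` (nm), the window used, and the number of bins.
#' @export
tail_decay_length <- function(profile, fit = NULL, min_dist = 2,
                              max_dist = 6) {
  if (is.null(fit)) {
    # single rising interface across the whole support
    half <- fit_half_tanh(profile$x, profile$c, rising = TRUE)
    L <- half$L
    x0 <- half$x0
    c1 <- half$c1
  } else {
    L <- fit$L
    x0 <- fit$x0[["left"]]
    c1 <- fit$c1
  }
  sel <- profile$x >= x0 - max_dist * L & profile$x <= x0 - min_dist * L
  y <- profile$c[sel] - c1
  x <- profile$x[sel]
  keep <- is.finite(y) & y > 0
  if (sum(keep) < 3)
    stop("too few tail bins between ", min_dist, "L and ", max_dist,
         "L from the interface")
  sl <- coef(stats::lm(log(y[keep]) ~ x[keep]))[[2]]
  if (sl <= 0) stop("tail does not decay away from the interface")
  list(xi = 1 / sl, n_bins = sum(keep),
       window = c(x0 - max_dist * L, x0 - min_dist * L))
}

#' Bulk correlation length from density fluctuations
#'
#' Estimates the correlation length inside a bulk region (far from both
#' interfaces) from the low-k structure factor of the one-dimensional
#' density fluctuations, assuming the Ornstein-Zernike form
#' `S(k) = S0 / (1 + k^2 xi^2)`: a linear fit of 1/S against k^2 gives
#' `xi^2` as slope/intercept.  Uncorrelated (ideal-gas) positions give a
#' flat S(k) and hence xi near 0.
#'
#' @param traj A `trajectory`.
#' @param bulk_region Length-2 numeric: x-interval (nm) of the bulk
#'   region, which must exclude the interfaces.
#' @param bin_width Bin width, nm.
#' @param n_modes Number of low-k modes used in the fit.
#' @return List with `xi` (nm), `se`, and the averaged structure factor
#'   (`data.frame(k, S)`).
#' @export
bulk_correlation_length <- function(traj, bulk_region, bin_width = 1,
                                    n_modes = 8) {
  if (length(traj$frames) < 4) stop("too few frames for a stable S(k)")
  lo <- bulk_region[1]
  hi <- bulk_region[2]
  W <- hi - lo
  n_bins <- max(8L, round(W / bin_width))
  bw <- W / n_bins
  Lx <- traj$box[1]
  spec_sum <- numeric(n_bins)
  nf <- 0L
  for (fr in traj$frames) {
    x <- fr[, 1] %% Lx
    x <- x[x >= lo & x < hi]
    cnt <- tabulate(pmin(floor((x - lo) / bw) + 1L, n_bins), nbins = n_bins)
    dc <- cnt - mean(cnt)
    spec_sum <- spec_sum + Mod(fft(dc))^2 / n_bins
    nf <- nf + 1L
  }
  S <- spec_sum / nf
  k <- 2 * pi * seq_len(n_bins %/% 2) / W
  S <- S[2:(n_bins %/% 2 + 1)]
  m <- min(n_modes, length(k))
  kk <- k[seq_len(m)]
  ss <- S[seq_len(m)]
  if (any(ss <= 0)) stop("degenerate structure factor")
  fitlm <- stats::lm(I(1 / ss) ~ I(kk^2))
  a <- coef(fitlm)[[1]]
  b <- coef(fitlm)[[2]]
  xi2 <- if (a > 0) max(b / a, 0) else 0
  vc <- stats::vcov(fitlm)
  # delta method on xi = sqrt(b/a)
  se <- if (xi2 > 0 && a > 0) {
    g <- c(-b / a^2, 1 / a)  # d(xi^2)
    se_xi2 <- sqrt(drop(t(g) %*% vc %*% g))
    se_xi2 / (2 * sqrt(xi2))
  } else NA_real_
  list(xi = sqrt(xi2), se = se, S = data.frame(k = k, S = S))
}

#' Radius of gyration of the chains
#'
#' Unwraps each chain through the periodic boundaries by bond continuity
#' (each bead is placed at the minimum-image displacement from its
#' predecessor), then averages the per-chain, per-frame radius of
#' gyration.  The SEM is taken over frame means by block averaging.
#'
#' @param traj A `trajectory`.
#' @param ff A [force_field()] (used to flag wrap artifacts: unwrapped
#'   bonds longer than R0).
#' @return List with `mean` (nm), `sem`, and `per_frame` means.
#' @export
radius_of_gyration <- function(traj, ff = force_field()) {
  if (!length(traj$frames)) stop("empty trajectory")
  topo <- traj$topology
  chains <- split(seq_len(topo$n_beads), topo$chain)
  box <- traj$box
  per_frame <- vapply(traj$frames, function(fr) {
    rgs <- vapply(chains, function(idx) {
      p <- fr[idx, , drop = FALSE]
      if (nrow(p) > 1) {
        d <- diff(p)
        for (j in 1:3) d[, j] <- d[, j] - box[j] * round(d[, j] / box[j])
        cum <- apply(d, 2, cumsum)
        if (is.null(dim(cum))) cum <- matrix(cum, nrow = 1)
        p <- rbind(p[1, , drop = FALSE], sweep(cum, 2, p[1, ], "+"))
      }
      ctr <- colMeans(p)
      sqrt(mean(rowSums(sweep(p, 2, ctr)^2)))
    }, numeric(1))
    mean(rgs)
  }, numeric(1))
  bl <- max(bond_lengths(list(positions = traj$frames[[length(traj$frames)]],
                              box = box, topology = topo)))
  if (bl >= ff$r0)
    warning("unwrapped bond longer than R0: wrap artifacts suspected")
  list(mean = mean(per_frame), sem = block_sem(per_frame),
       per_frame = per_frame)
}
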