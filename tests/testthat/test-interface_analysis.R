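test_that("Kirkwood-Buff gamma: isotropic series give zero, constant anisotropy the exact arithmetic", {
  iso <- data.frame(px = rep(0.2, 50), py = rep(0.2, 50), pz = rep(0.2, 50))
  expect_equal(kirkwood_buff_gamma(iso, lx = 250)$gamma, 0)

  an <- data.frame(px = 0.2 + 1e-3, py = 0.2, pz = 0.2)[rep(1, 50), ]
  est <- kirkwood_buff_gamma(an, lx = 250)
  expect_equal(est$gamma, 0.125, tolerance = 1e-12)
  # unit conversion: 1 kBT0/nm^2 = kB * 300 / 1e-18 N/m
  expect_equal(est$gamma_si / est$gamma, 1.380649e-23 * 300 * 1e18,
               tolerance = 1e-12)
})

test_that("gamma estimate is invariant under y<->z relabeling and recovers AR(1) truth", {
  g <- gen_pressure_series(mean_anisotropy = 2e-3, ac_time = 4,
                           sigma = 0.02, n = 4000, lx = 250, seed = 77)
  est <- kirkwood_buff_gamma(g$samples, lx = 250)
  swapped <- g$samples
  names(swapped)[names(swapped) == "py"] <- "tmp"
  names(swapped)[names(swapped) == "pz"] <- "py"
  names(swapped)[names(swapped) == "tmp"] <- "pz"
  expect_equal(kirkwood_buff_gamma(swapped, lx = 250)$gamma, est$gamma)
  # recovery within 2 analytic SEM
  expect_lt(abs(est$gamma - g$truth$gamma), 2 * g$truth$sem_gamma)
})

test_that("multi-repeat gamma uses the SEM across repeats", {
  reps <- lapply(1:5, function(s)
    gen_pressure_series(mean_anisotropy = 1e-3, ac_time = 3, sigma = 0.01,
                        n = 500, lx = 250, seed = s)$samples)
  est <- kirkwood_buff_gamma(reps, lx = 250)
  expect_equal(est$n_repeats, 5)
  per <- vapply(reps, function(s)
    125 * mean(s$px - 0.5 * (s$py + s$pz)), numeric(1))
  expect_equal(est$gamma, mean(per))
  expect_equal(est$sem, sd(per) / sqrt(5))
})

test_that("density profiles conserve bead count and handle degenerate inputs", {
  # uniform beads: flat within Poisson noise
  u <- gen_toy_trajectory("uniform", n_beads = 4000, box = c(100, 10, 10),
                          n_frames = 5, seed = 3)$trajectory
  prof <- bin_profile(u, bin_width = 2, recenter = FALSE)
  binvol <- attr(prof, "bin_width") * 100
  expect_equal(sum(prof$c) * binvol, 4000, tolerance = 1e-9)
  lambda <- 4000 / 50  # beads per bin per frame
  expect_lt(max(abs(prof$c - mean(prof$c))) / mean(prof$c),
            6 * sqrt(lambda * 5) / (lambda * 5))

  # all beads at one x: a single occupied bin
  pt <- gen_toy_trajectory("point", n_beads = 100,
                           box = c(100, 10, 10))$trajectory
  p2 <- bin_profile(pt, bin_width = 1, recenter = FALSE)
  expect_equal(sum(p2$c > 0), 1)

  expect_error(bin_profile(structure(list(frames = list(), box = c(10, 5, 5)),
                                     class = "trajectory")), "empty")
})

test_that("recentering a drifting slab sharpens the fitted interface", {
  # synthetic slab whose center drifts frame to frame
  set.seed(12)
  box <- c(120, 10, 10)
  n <- 3000
  frames <- lapply(1:30, function(i) {
    center <- 60 + 12 * sin(i / 3) + cumsum(rnorm(1, 0, 2))
    x <- (rnorm(n, center, 6)) %% box[1]
    cbind(x, runif(n, 0, 10), runif(n, 0, 10))
  })
  topo <- list(types = rep(1L, n), bonds = matrix(integer(0), 0, 2),
               chain = seq_len(n), n_beads = n)
  traj <- structure(list(frames = frames, times = 1:30, box = box,
                         topology = topo, temperature = NA),
                    class = "trajectory")
  f_re <- fit_tanh(bin_profile(traj, recenter = TRUE))
  f_no <- fit_tanh(bin_profile(traj, recenter = FALSE))
  expect_lt(f_re$L, f_no$L)
})

test_that("tanh fits recover noiseless generated profiles exactly", {
  g <- gen_tanh_profile(c1 = 0.1, c2 = 5, x0 = 60, L = 8, lx = 250,
                        noise = 0, two_interface = TRUE)
  fit <- fit_tanh(g$profile)
  expect_equal(fit$c1, 0.1, tolerance = 1e-6)
  expect_equal(fit$c2, 5, tolerance = 1e-6)
  expect_equal(fit$L, 8, tolerance = 1e-5)
  expect_equal(unname(fit$x0), c(60, 190), tolerance = 1e-5)
  # the two half-fits agree by symmetry
  expect_equal(fit$halves$left$L, fit$halves$right$L, tolerance = 1e-6)
  # predict() reproduces the profile
  expect_lt(max(abs(predict(fit) - g$profile$c)), 1e-6)
})

test_that("tanh fit is shift-equivariant and rejects flat profiles", {
  g1 <- gen_tanh_profile(c1 = 0.2, c2 = 3, x0 = 55, L = 6, lx = 200,
                         two_interface = TRUE)
  g2 <- gen_tanh_profile(c1 = 0.2, c2 = 3, x0 = 65, L = 6, lx = 200,
                         two_interface = TRUE)
  f1 <- fit_tanh(g1$profile)
  f2 <- fit_tanh(g2$profile)
  expect_equal(f2$x0[["left"]] - f1$x0[["left"]], 10, tolerance = 1e-4)
  expect_equal(f1$L, f2$L, tolerance = 1e-5)
  expect_equal(f1$c2, f2$c2, tolerance = 1e-6)

  flat <- as_density_profile(seq(0.5, 99.5), rep(2, 100), c(100, 10, 10))
  expect_error(fit_tanh(flat), "plateaus")
})

test_that("noisy width estimates are unbiased (Monte-Carlo)", {
  ests <- vapply(1:60, function(s) {
    g <- gen_tanh_profile(c1 = 0.1, c2 = 5, x0 = 60, L = 8, lx = 250,
                          noise = 0.05, two_interface = TRUE,
                          seed = s)
    fit_tanh(g$profile)$L
  }, numeric(1))
  expect_lt(abs(mean(ests) - 8), 2 * sd(ests) / sqrt(length(ests)))
})

test_that("interface width maps to correlation length as L/4", {
  expect_equal(xi_from_width(8), 2)
  expect_equal(xi_from_width(1e-9), 2.5e-10)
  expect_error(xi_from_width(-1), "positive")
})

test_that("the far-field tail of a tanh profile decays with length L/4", {
  g <- gen_tanh_profile(c1 = 0.05, c2 = 4, x0 = 100, L = 10, lx = 250,
                        bin_width = 0.25, noise = 0, two_interface = FALSE)
  td <- tail_decay_length(g$profile)
  expect_rel_equal(td$xi, 10 / 4, 1e-3)
  # holds across widths (analytic identity, tested numerically)
  for (L in c(4, 8, 16)) {
    gi <- gen_tanh_profile(c1 = 0.05, c2 = 4, x0 = 120, L = L, lx = 300,
                           bin_width = 0.25, two_interface = FALSE)
    expect_rel_equal(tail_decay_length(gi$profile)$xi, L / 4, 1e-3)
  }
})

test_that("bulk correlation length: white noise gives ~0, OZ field is recovered", {
  gas <- gen_toy_trajectory("uniform", n_beads = 2000, box = c(64, 15, 15),
                            n_frames = 80, seed = 5)$trajectory
  b0 <- bulk_correlation_length(gas, bulk_region = c(0, 64))
  expect_lt(b0$xi, 0.8)

  oz <- gen_oz_field(xi = 3, width = 64, n_frames = 250, seed = 8)
  b3 <- bulk_correlation_length(oz$trajectory, bulk_region = c(0, 64))
  expect_rel_equal(b3$xi, 3, 0.15)
})

test_that("radius of gyration matches closed forms and unwraps chains", {
  rod <- gen_toy_trajectory("rod", n_beads = 24, spacing = 1)
  rg <- radius_of_gyration(rod$trajectory)
  expect_equal(rg$mean, sqrt((24^2 - 1) / 12), tolerance = 1e-12)

  pt <- gen_toy_trajectory("point", n_beads = 10)
  expect_equal(radius_of_gyration(pt$trajectory)$mean, 0)

  # chain wrapped through the periodic boundary: Rg must match the
  # unwrapped rod value
  box <- c(20, 10, 10)
  x <- seq(16.5, 25.5, by = 1) %% 20  # 10 beads crossing the wall
  pos <- cbind(x, rep(5, 10), rep(5, 10))
  topo <- build_topology(polymer_spec(1, 10), 1)
  traj <- structure(list(frames = list(pos), times = 1, box = box,
                         topology = topo, temperature = NA),
                    class = "trajectory")
  expect_equal(radius_of_gyration(traj)$mean, sqrt((10^2 - 1) / 12),
               tolerance = 1e-12)
})
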