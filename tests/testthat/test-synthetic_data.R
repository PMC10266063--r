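test_that("generators are seed-deterministic and ship their ground truth", {
  a <- gen_tanh_profile(noise = 0.05, seed = 4)
  b <- gen_tanh_profile(noise = 0.05, seed = 4)
  expect_identical(a$profile$c, b$profile$c)
  expect_false(identical(a$profile$c,
                         gen_tanh_profile(noise = 0.05, seed = 5)$profile$c))
  expect_equal(a$truth$xi, a$truth$L / 4)

  p1 <- gen_pressure_series(seed = 2)
  p2 <- gen_pressure_series(seed = 2)
  expect_identical(p1$samples, p2$samples)

  g1 <- gen_powerlaw_gamma(seed = 3)
  expect_identical(g1$table, gen_powerlaw_gamma(seed = 3)$table)

  o1 <- gen_oz_field(n_frames = 3, seed = 6)
  o2 <- gen_oz_field(n_frames = 3, seed = 6)
  expect_identical(o1$trajectory$frames, o2$trajectory$frames)
})

test_that("generator RNG state does not leak into the session", {
  set.seed(99)
  before <- .Random.seed
  invisible(gen_powerlaw_gamma(seed = 1))
  expect_identical(.Random.seed, before)
})

test_that("zero-noise round trips are exact for every generator/fitter pair", {
  # tanh profile -> fit_tanh
  g <- gen_tanh_profile(c1 = 0.2, c2 = 4, x0 = 70, L = 9, lx = 250,
                        noise = 0, two_interface = TRUE)
  f <- fit_tanh(g$profile)
  expect_equal(coef(f)[c("c1", "c2", "L")],
               c(c1 = 0.2, c2 = 4, L = 9), tolerance = 1e-5)

  # power-law table -> fit_power_law
  pg <- gen_powerlaw_gamma(tc = 330, gamma0 = 1.5, noise = 0, seed = 1)
  pf <- fit_power_law(pg$table$temperature, pg$table$gamma)
  expect_equal(pf$tc, 330, tolerance = 1e-7)
  expect_equal(pf$amplitude, 1.5, tolerance = 1e-7)

  # noise-free pressure series -> Kirkwood-Buff
  ps <- gen_pressure_series(mean_anisotropy = 5e-4, sigma = 0, n = 100,
                            lx = 200, seed = 1)
  expect_equal(kirkwood_buff_gamma(ps$samples, 200)$gamma, ps$truth$gamma,
               tolerance = 1e-14)
})

test_that("a two-point temperature grid is rejected by the fitter", {
  g <- gen_powerlaw_gamma(t_grid = c(250, 280), noise = 0, seed = 1)
  expect_error(fit_power_law(g$table$temperature, g$table$gamma),
               "insufficient")
})

test_that("zero-mean anisotropy gives gamma consistent with zero", {
  g <- gen_pressure_series(mean_anisotropy = 0, ac_time = 4, sigma = 0.01,
                           n = 2000, lx = 250, seed = 11)
  est <- kirkwood_buff_gamma(g$samples, 250)
  expect_lt(abs(est$gamma), 2 * g$truth$sem_gamma)
})

test_that("block-averaged SEM tracks the analytic AR(1) standard error", {
  # across seeds, the block SEM should be an approximately unbiased
  # estimate of the true AR(1) error of the mean
  sems <- vapply(1:60, function(s) {
    g <- gen_pressure_series(mean_anisotropy = 1e-3, ac_time = 5,
                             sigma = 0.01, n = 2000, lx = 250, seed = s)
    kirkwood_buff_gamma(g$samples, 250)$sem
  }, numeric(1))
  truth <- gen_pressure_series(mean_anisotropy = 1e-3, ac_time = 5,
                               sigma = 0.01, n = 2000, lx = 250,
                               seed = 1)$truth$sem_gamma
  expect_rel_equal(mean(sems), truth, 0.2)
})

test_that("OZ field spectra carry the imposed correlation length", {
  oz <- gen_oz_field(xi = 3, width = 64, n_frames = 200, seed = 13)
  est <- bulk_correlation_length(oz$trajectory, bulk_region = c(0, 64))
  expect_rel_equal(est$xi, 3, 0.15)
  # white-noise limit
  w <- gen_oz_field(xi = 0, width = 64, n_frames = 100, seed = 14)
  expect_lt(bulk_correlation_length(w$trajectory,
                                    bulk_region = c(0, 64))$xi, 0.8)
})

test_that("toy trajectories reproduce closed-form Rg to machine precision", {
  rod <- gen_toy_trajectory("rod", n_beads = 17, spacing = 1.3)
  expect_equal(radius_of_gyration(rod$trajectory)$mean,
               1.3 * sqrt((17^2 - 1) / 12), tolerance = 1e-12)
  expect_equal(rod$truth$rg, 1.3 * sqrt((17^2 - 1) / 12))
})

test_that("confidence-interval coverage of tanh width fits is calibrated", {
  # 95 percent CIs from the fit covariance should cover the true width
  # in ~95 percent of noisy replicates
  n_rep <- 200
  cover <- logical(n_rep)
  for (s in seq_len(n_rep)) {
    g <- gen_tanh_profile(c1 = 0.1, c2 = 5, x0 = 60, L = 8, lx = 250,
                          noise = 0.05, two_interface = TRUE,
                          seed = 1000 + s)
    f <- fit_tanh(g$profile)
    ci <- f$L + c(-1.96, 1.96) * f$se[["L"]]
    cover[s] <- ci[1] <= 8 && 8 <= ci[2]
  }
  expect_gte(mean(cover), 0.95 - 0.04)
  expect_lte(mean(cover), 1)
})
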