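test_that("universal constants satisfy their exact identities", {
  cst <- ising_constants()
  expect_identical(cst$nu, cst$mu / (cst$dims - 1))
  expect_equal(cst$nu, 0.63)
  expect_equal(gamma_coefficient(), 0.1024 * 16)
  expect_equal(signif(gamma_coefficient(), 3), 1.64)
})

test_that("reduced temperature arithmetic", {
  expect_equal(reduced_temperature(300, 300), 0)
  expect_equal(reduced_temperature(240, 300), 0.2)
  expect_lt(reduced_temperature(320, 300), 0)  # supercritical
  expect_error(reduced_temperature(300, -1), "positive")
})

test_that("finite-size filter keeps xi < 0.05 Lx and demands 3 survivors", {
  pts <- data.frame(temperature = c(200, 210, 220, 240, 260),
                    y = c(1, 1.5, 2, 3, 4),
                    xi = c(11, 12, 12.49, 12.5, 13))
  out <- finite_size_filter(pts, lx = 250)
  expect_equal(out$retained$xi, c(11, 12, 12.49))  # strict: 12.5 excluded
  expect_equal(nrow(out$excluded), 2)
  expect_match(out$excluded$reason[1], "Lx")
  expect_error(finite_size_filter(
    data.frame(temperature = 1:4, y = 1:4, xi = rep(20, 4)), lx = 250),
    "filter")
})

test_that("power-law fits recover noiseless generative truth exactly", {
  tt <- seq(240, 300, by = 10)
  # gamma branch: y = 2 (1 - T/320)^1.26
  y <- 2 * (1 - tt / 320)^1.26
  f <- fit_power_law(tt, y, kind = "gamma")
  expect_equal(f$tc, 320, tolerance = 1e-8)
  expect_equal(f$amplitude, 2, tolerance = 1e-8)
  # xi branch: L = 4 * 0.5 * tau^(-0.63)  =>  xi0 = 0.5 on L/4
  L <- 4 * 0.5 * (1 - tt / 320)^(-0.63)
  fx <- fit_power_law(tt, L / 4, kind = "xi")
  expect_equal(fx$tc, 320, tolerance = 1e-8)
  expect_equal(fx$amplitude, 0.5, tolerance = 1e-8)
  # predict() closes the loop
  expect_equal(predict(f, tt), y, tolerance = 1e-8)
})

test_that("power-law fit is scale-equivariant and rejects bad inputs", {
  tt <- seq(240, 300, by = 10)
  y <- 1.3 * (1 - tt / 315)^1.26
  f1 <- fit_power_law(tt, y)
  f2 <- fit_power_law(tt, 10 * y)
  expect_equal(f2$tc, f1$tc, tolerance = 1e-7)
  expect_equal(f2$amplitude / f1$amplitude, 10, tolerance = 1e-7)
  expect_error(fit_power_law(c(250, 260), y[1:2]), "insufficient")
})

test_that("Tc recovery from noisy synthetic tables is unbiased and covered", {
  # Monte-Carlo at the generator's default noise and point spacing
  n_rep <- 200
  hits <- 0
  errs <- numeric(n_rep)
  for (s in seq_len(n_rep)) {
    g <- gen_powerlaw_gamma(tc = 320, gamma0 = 2, noise = 0.05,
                            n_repeats = 5, seed = s)
    f <- fit_power_law(g$table$temperature, g$table$gamma, g$table$sem)
    errs[s] <- f$tc - 320
    ci <- confint(f, "tc")
    if (ci[1] <= 320 && 320 <= ci[2]) hits <- hits + 1
  }
  expect_lt(abs(mean(errs)), 1)                 # Tc bias < 1 K
  # coverage not significantly below the 90 percent requirement
  expect_gt(stats::binom.test(hits, n_rep, 0.9,
                              alternative = "less")$p.value, 0.01)
})

test_that("collapse puts exact power laws on tau^mu out to the largest tau", {
  tt <- seq(230, 300, by = 10)
  mu <- ising_constants()$mu
  y1 <- 2.0 * (1 - tt / 320)^mu
  y2 <- 0.7 * (1 - tt / 340)^mu
  f1 <- fit_power_law(tt, y1)
  f2 <- fit_power_law(tt, y2)
  coll <- collapse_and_extent(
    list(a = data.frame(temperature = tt, gamma = y1),
         b = data.frame(temperature = tt, gamma = y2)),
    list(f1, f2))
  expect_lt(max(coll$table$deviation), 1e-6)
  expect_equal(unname(coll$tau_star["a"]), max(1 - tt / 320),
               tolerance = 1e-8)
  # two series from the same generator collapse onto identical curves
  sa <- coll$table[coll$table$series == "a", ]
  sb <- coll$table[coll$table$series == "b", ]
  expect_equal(sa$scaled_gamma, (sa$tau)^mu, tolerance = 1e-6)
  expect_equal(sb$scaled_gamma, (sb$tau)^mu, tolerance = 1e-6)
})

test_that("an imposed crossover bounds the detected critical-regime extent", {
  g <- gen_powerlaw_gamma(tc = 320, gamma0 = 2,
                          t_grid = seq(200, 300, by = 5), noise = 0,
                          crossover_tau = 0.25, deviation = 0.30, seed = 1)
  # fit on the sub-crossover points only (the regime the fit describes)
  sub <- g$table[1 - g$table$temperature / 320 <= 0.25, ]
  f <- fit_power_law(sub$temperature, sub$gamma)
  coll <- collapse_and_extent(
    data.frame(temperature = g$table$temperature, gamma = g$table$gamma),
    f, rel_tol = 0.10)
  expect_gte(coll$tau_star_pooled, 0.2)
  expect_lte(coll$tau_star_pooled, 0.3)
})

test_that("iterative finite-size filtering converges and reports exclusions", {
  tt <- seq(230, 310, by = 10)
  tc <- 320
  tau <- 1 - tt / tc
  gam <- 2 * tau^1.26
  L <- 4 * 0.5 * tau^(-0.63)
  tab <- data.frame(temperature = tt, y = gam, sem = rep(0.01, length(tt)),
                    xi = L / 4)
  fit <- fit_critical(tab, lx = 80, kind = "gamma")
  expect_true(all(fit$retained$xi < 4))
  expect_true(all(fit$excluded$xi >= 4))
  expect_gt(nrow(fit$excluded), 0)  # near-critical points must drop out
  expect_equal(fit$tc, 320, tolerance = 0.5)
})

test_that("universal-ratio prediction reproduces its closed-form examples", {
  # Tc = 300 K, L = 100 nm  ->  gamma ~ 6.8e-7 N/m
  p <- gamma_from_universal_ratio(tc = 300, t_ref = 260, l_ref = 12)
  g100 <- 1.6384 * 1.380649e-23 * 300 / (100e-9)^2
  expect_equal(g100, 6.787e-7, tolerance = 1e-3)
  # gamma(T) = 16 R- kB Tc / L(T)^2 at the reference point itself
  gam_ref <- predict(p, 260)
  expect_equal(gam_ref, 1.6384 * 1.380649e-23 * 300 / (12e-9)^2,
               tolerance = 1e-10)
  # gamma -> 0 at Tc
  expect_lt(predict(p, 299.9), 1e-3 * p$gamma0_si)
  expect_error(gamma_from_universal_ratio(300, 310, 12), "below Tc")
})

test_that("prediction pipeline closes: fitting its own output returns the inputs", {
  p <- gamma_from_universal_ratio(tc = 310, t_ref = 250, l_ref = 15)
  tt <- seq(230, 300, by = 10)
  f <- fit_power_law(tt, predict(p, tt), kind = "gamma")
  expect_equal(f$tc, 310, tolerance = 1e-6)
  expect_equal(f$amplitude, p$gamma0_si, tolerance = 1e-6 * p$gamma0_si)
})

test_that("validation flags agreement and constructed violations", {
  p <- gamma_from_universal_ratio(tc = 310, t_ref = 250, l_ref = 15)
  tt <- seq(240, 290, by = 10)
  truth <- predict(p, tt)
  direct <- data.frame(temperature = tt, gamma = truth,
                       sem = 0.05 * truth)
  v <- validate_prediction(direct, p, units = "si")
  expect_true(v$consistent)
  expect_equal(v$table$ratio, rep(1, length(tt)))

  # gamma inflated threefold must be flagged
  bad <- direct
  bad$gamma <- 3 * truth
  expect_false(validate_prediction(bad, p, units = "si")$consistent)
})
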