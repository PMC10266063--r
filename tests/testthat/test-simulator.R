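test_that("slab initialization confines beads and keeps bonds short", {
  spec <- polymer_spec(3, 12)
  sim <- scaled_down_config(temperature = 200, seed = 2)
  cfg <- init_slab(spec, sim)
  half <- sim$slab_half_width
  cx <- sim$box[1] / 2
  expect_true(all(abs(cfg$positions[, 1] - cx) <= half + 1e-9))
  expect_equal(nrow(cfg$positions), 64 * 12)
  b <- cfg$positions[cfg$topology$bonds[, 1], ] -
    cfg$positions[cfg$topology$bonds[, 2], ]
  expect_true(all(sqrt(rowSums(b^2)) < 0.5 * force_field()$r0))

  # single polymer placed trivially
  sim1 <- simulation_config(n_polymers = 1, box = c(40, 10, 10),
                            temperature = 300, slab_half_width = 10)
  cfg1 <- init_slab(polymer_spec(3, 24), sim1)
  expect_equal(nrow(cfg1$positions), 24)

  # geometric impossibility
  sim_bad <- simulation_config(n_polymers = 4, box = c(30, 10, 10),
                               temperature = 300, slab_half_width = 20)
  expect_error(init_slab(polymer_spec(3, 12), sim_bad), "half-width")
})

test_that("thermostat reaches equipartition: free bead and bonded chains", {
  # single free bead: velocity variance per axis = kB T / m
  sim <- quick_sim(1, c(20, 8, 8), temperature = 260, seed = 3,
                   production = 2e5, sample_every = 50)
  cfg <- free_bead_config(matrix(c(5, 4, 4), 1, 3), c(20, 8, 8))
  run <- run_langevin(cfg, force_field(), sim, save_frames = FALSE)
  # ekin samples are (3/2) kT in kB*T0 units on average
  target <- 1.5 * 260 / 300
  expect_rel_equal(mean(run$ekin), target, 0.05)

  # interacting chains: kinetic temperature within 2 percent of target
  spec <- polymer_spec(2, 8)
  simc <- quick_sim(8, c(30, 10, 10), temperature = 220, seed = 5,
                    production = 5e4, sample_every = 20)
  cfg8 <- init_slab(spec, simconfig_with_half(simc, 10))
  runc <- run_langevin(cfg8, force_field(), simc, save_frames = FALSE)
  tkin <- 300 * 2 * mean(runc$ekin[-(1:50)]) / (3 * cfg8$topology$n_beads)
  expect_rel_equal(tkin, 220, 0.02)
})

test_that("dimer bond statistics match the Boltzmann distribution", {
  # A-B dimer with the attraction switched off isolates the bond term:
  # p(r) dr ~ r^2 exp(-U_b(r)/kT) dr
  ff <- force_field()
  temp <- 260
  kt <- temp / 300
  sim <- quick_sim(1, c(20, 20, 20), temperature = temp, seed = 9,
                   production = 4e5, sample_every = 200)
  topo <- build_topology(polymer_spec(1, 2), 1)
  cfg <- system_configuration(rbind(c(10, 10, 10), c(10.8, 10, 10)),
                              c(20, 20, 20), topo)
  run <- run_langevin(cfg, ff, sim, u0_scale = 0, save_frames = TRUE)
  r <- vapply(run$trajectory$frames, function(fr)
    sqrt(sum((fr[1, ] - fr[2, ])^2)), numeric(1))

  dens <- function(x) x^2 * exp(-bond_energy(x, ff) / kt)
  znorm <- stats::integrate(dens, 0, ff$r0 - 1e-9)$value
  # mean bond energy vs quadrature, within 3 SEM
  e_mean_th <- stats::integrate(function(x)
    bond_energy(x, ff) * dens(x) / znorm, 0, ff$r0 - 1e-9)$value
  e_obs <- bond_energy(r, ff)
  n_eff <- length(r)  # samples 2 ns apart: uncorrelated (tau_v = 1 ns)
  expect_lt(abs(mean(e_obs) - e_mean_th), 3 * sd(e_obs) / sqrt(n_eff))

  # full-distribution check (Kolmogorov-Smirnov, alpha = 0.01)
  cdf <- function(q) vapply(q, function(qi)
    stats::integrate(dens, 0, qi)$value / znorm, numeric(1))
  ks <- stats::ks.test(r, cdf)
  expect_gt(ks$p.value, 0.01)
})

test_that("identical seed and configuration give bitwise-identical output", {
  spec <- polymer_spec(2, 8)
  sim <- quick_sim(4, c(30, 10, 10), temperature = 250, seed = 123,
                   production = 2e3, sample_every = 100)
  cfg <- init_slab(spec, simconfig_with_half(sim, 10))
  r1 <- run_langevin(cfg, force_field(), sim)
  r2 <- run_langevin(cfg, force_field(), sim)
  expect_identical(r1$config$positions, r2$config$positions)
  expect_identical(r1$pressure, r2$pressure)
  # a different seed decorrelates
  sim2 <- sim
  sim2$seed <- 124L
  r3 <- run_langevin(cfg, force_field(), sim2)
  expect_false(identical(r1$config$positions, r3$config$positions))
})

test_that("energy is conserved with the thermostat off", {
  spec <- polymer_spec(2, 8)
  sim <- quick_sim(4, c(30, 10, 10), temperature = 150, seed = 31,
                   production = 1e4, sample_every = 100)
  cfg <- init_slab(spec, simconfig_with_half(sim, 10))
  warm <- run_langevin(cfg, force_field(), sim, n_steps = 5e3,
                       save_frames = FALSE)
  nve <- run_langevin(warm$config, force_field(), sim, n_steps = 5e4,
                      sample_every = 100, save_frames = FALSE,
                      thermostat = FALSE)
  etot <- nve$ekin + nve$epot
  scale <- max(abs(mean(etot)), mean(nve$ekin))
  # secular drift per 1e4 steps (instantaneous energy also carries a
  # bounded discretization wander, which is not drift)
  slope <- coef(stats::lm(etot ~ seq_along(etot)))[[2]] * 100
  expect_lt(abs(slope) / scale, 1e-4)
})

test_that("pressure tensor is exactly kinetic for non-interacting beads", {
  box <- c(20, 10, 10)
  pos <- rbind(c(2, 2, 2), c(10, 5, 5), c(18, 8, 8))  # far apart
  vel <- rbind(c(1, -2, 0.5), c(-0.3, 0.7, 1.1), c(0.2, 0.1, -0.9))
  cfg <- free_bead_config(pos, box, velocities = vel)
  p <- pressure_tensor(cfg)
  expect_equal(unname(p), colSums(vel^2) / prod(box), tolerance = 1e-14)
})

test_that("pair virial equals the box-strain derivative of the energy", {
  # single same-type pair inside the WCA range, plus a bonded A-B pair:
  # W_x must equal -dU/d(eps) under an affine strain x -> (1 + eps) x
  box <- c(20, 10, 10)
  ff <- force_field()
  cfg_rep <- free_bead_config(rbind(c(5, 5, 5), c(5.7, 5.3, 5.1)), box,
                              type = 1L)
  w <- evaluate_forces(cfg_rep, ff)$virial
  expect_rel_equal(w[1], strain_virial_oracle(cfg_rep, ff), 1e-5)

  # attracting A-B pair
  cfg_ab <- free_bead_config(rbind(c(5, 5, 5), c(5.6, 5.2, 5)), box,
                             type = c(1L, 2L))
  wab <- evaluate_forces(cfg_ab, ff)$virial
  expect_rel_equal(wab[1], strain_virial_oracle(cfg_ab, ff), 1e-5)

  # bonded pair (bond term only)
  topo <- build_topology(polymer_spec(1, 2), 1)
  cfg_bond <- system_configuration(rbind(c(5, 5, 5), c(8, 6, 5)), box, topo)
  w2 <- evaluate_forces(cfg_bond, ff, u0_scale = 0)$virial
  expect_rel_equal(w2[1], strain_virial_oracle(cfg_bond, ff, 0), 1e-5)
})

test_that("equilibration protocol scales its stages with the budget", {
  spec <- polymer_spec(3, 12)
  sim <- simulation_config(n_polymers = 4, box = c(40, 10, 10),
                           temperature = 240, seed = 8, budget = 2e-4,
                           slab_half_width = 10)
  expect_equal(unname(sim$schedule[c("slab_confine_steps", "ramp_steps",
                                     "equilibrate_steps")]),
               c(200, 200, 2000))
  eq <- equilibrate_protocol(spec, force_field(), sim)
  expect_false(eq$aborted)
  expect_equal(unique(eq$report$stage), c("confine", "ramp", "equilibrate"))
  # chains stayed inside the box and bonds are intact
  expect_true(all(is.finite(eq$config$positions)))
})

test_that("without attraction a dense slab relaxes toward uniform", {
  # dimers diffuse fast enough (D_cm = D/2) to decay visibly in the run
  spec <- polymer_spec(1, 2)
  sim <- quick_sim(48, c(60, 12, 12), temperature = 300, seed = 4,
                   production = 5e4, sample_every = 2500)
  cfg <- init_slab(spec, simconfig_with_half(sim, 8))
  run <- run_langevin(cfg, force_field(), sim, u0_scale = 0)
  lx <- sim$box[1]
  frac0 <- mean(abs(cfg$positions[, 1] - lx / 2) <= 10)
  last <- run$trajectory$frames[[n_frames(run$trajectory)]]
  xw <- last[, 1] %% lx
  frac1 <- mean(abs(xw - lx / 2) <= 10)  # uniform share would be 1/3
  expect_gt(frac0, 0.99)
  expect_lt(frac1, 0.62)
  expect_lt(frac1, frac0 - 0.3)
})
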