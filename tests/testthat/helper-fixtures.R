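# Small builders shared across test files.

# A short chain with modest random bond displacements, safe for force tests.
random_chain_config <- function(n_beads = 10, box = c(20, 8, 8), seed = 7,
                                ell = 1) {
  set.seed(seed)
  spec <- polymer_spec(ell, n_beads)
  topo <- build_topology(spec, 1)
  pos <- cbind(cumsum(runif(n_beads, -0.8, 0.8)) + box[1] / 2,
               cumsum(runif(n_beads, -0.8, 0.8)) + box[2] / 2,
               cumsum(runif(n_beads, -0.8, 0.8)) + box[3] / 2)
  system_configuration(pos, box, topo)
}

# Free beads (no bonds), optionally with prescribed velocities.
free_bead_config <- function(pos, box, velocities = NULL, type = 1L) {
  n <- nrow(pos)
  topo <- list(types = rep(as.integer(type), length.out = n),
               bonds = matrix(integer(0), 0, 2), chain = seq_len(n),
               n_beads = n)
  system_configuration(pos, box, topo, velocities = velocities)
}

# Minimal schedule helper: production-only run configs for tests.
quick_sim <- function(n_polymers, box, temperature, seed = 1,
                      production = 1e4, sample_every = 100) {
  simulation_config(n_polymers = n_polymers, box = box,
                    temperature = temperature, seed = seed,
                    schedule = c(slab_confine_steps = 1, ramp_steps = 1,
                                 equilibrate_steps = 1,
                                 production_steps = production,
                                 sample_every = sample_every))
}

# Memoized scaled-down phase-separated slab (shared by tests that need a
# real condensate; computed once per test session).
shared_slab <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- polymer_spec(3, 12)
      ff <- force_field()
      sim <- scaled_down_config(temperature = 140, seed = 11,
                                budget = 0.004)
      cache <<- c(slab_experiment(spec, ff, sim, n_repeats = 1),
                  list(spec = spec, ff = ff, sim = sim))
    }
    cache
  }
})

expect_rel_equal <- function(object, expected, tol) {
  expect_lt(abs(object - expected) / abs(expected), tol)
}

# Copy of a simulation_config with a different slab half-width.
simconfig_with_half <- function(sim, half) {
  sim$slab_half_width <- half
  sim
}

# Independent oracle for the pair virial: -dU/d(strain) under an affine
# strain of the x axis (coordinates and box scaled together).
strain_virial_oracle <- function(cfg, ff, u0_scale = 1, h = 1e-6) {
  en <- function(s) {
    p <- cfg$positions
    p[, 1] <- p[, 1] * (1 + s)
    c2 <- system_configuration(p, c(cfg$box[1] * (1 + s), cfg$box[2],
                                    cfg$box[3]), cfg$topology)
    evaluate_forces(c2, ff, u0_scale = u0_scale)$energy
  }
  -(en(h) - en(-h)) / (2 * h)
}
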