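#' Evaluate code with a temporarily fixed RNG state
#'
#' Uses Mersenne-Twister / inversion regardless of the session default, so
#' generator output is reproducible across platforms, and restores the
#' caller's RNG state on exit.
#' @keywords internal
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion")
  force(code)
}

# Derive a stage-specific 31-bit seed from the run seed.
stage_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 48271 + stage * 1000003) %% 2147483647)
}

#' Simulation run configuration
#'
#' Holds the box, temperature, Langevin parameters and step schedule of a
#' slab simulation.  The timestep is tied to the velocity relaxation time
#' as `tau_v / 100`.  The bead mass is the internal mass unit (m = 1 in
#' kB*T0 ns^2 / nm^2), so the friction coefficient is `zeta = m / tau_v`
#' and thermal velocities are `sqrt(T/T0)` nm/ns.
#'
#' @param n_polymers Number of chains.
#' @param box Box edge lengths (Lx, Ly, Lz), nm; x is the long axis normal
#'   to the slab interfaces.
#' @param temperature Thermostat temperature, K.
#' @param tau_v Velocity relaxation time, ns.
#' @param seed Integer seed controlling thermostat noise and initial
#'   velocities.
#' @param schedule Named numeric vector of step counts:
#'   `slab_confine_steps`, `ramp_steps`, `equilibrate_steps`,
#'   `production_steps`, `sample_every`.  Defaults follow the full-scale
#'   protocol (1e6 / 1e6 / 1e7 / 5e7, sampled every 1e5 steps).
#' @param budget Dimensionless factor scaling every stage's step count
#'   (and the sampling stride) for scaled-down runs.
#' @param slab_half_width Half-width of the initial slab confinement along
#'   x, nm.
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(n_polymers = 625,
                              box = c(250, 30, 30),
                              temperature = 260,
                              tau_v = 1,
                              seed = 1,
                              schedule = c(slab_confine_steps = 1e6,
                                           ramp_steps = 1e6,
                                           equilibrate_steps = 1e7,
                                           production_steps = 5e7,
                                           sample_every = 1e5),
                              budget = 1,
                              slab_half_width = 40) {
  need <- c("slab_confine_steps", "ramp_steps", "equilibrate_steps",
            "production_steps", "sample_every")
  if (!all(need %in% names(schedule))) stop("schedule missing entries")
  sched <- round(schedule[need] * budget)
  sched[sched < 1] <- 1
  if (sched["production_steps"] %% sched["sample_every"] != 0)
    sched["production_steps"] <-
      ceiling(sched["production_steps"] / sched["sample_every"]) *
      sched["sample_every"]
  if (temperature <= 0) stop("temperature must be positive (K)")
  structure(list(n_polymers = n_polymers, box = as.numeric(box),
                 temperature = temperature, tau_v = tau_v,
                 timestep = tau_v / 100, mass = 1, seed = as.integer(seed),
                 schedule = sched, slab_half_width = slab_half_width),
            class = "simulation_config")
}

#' Scaled-down slab preset for quick runs
#'
#' 64 polymers of length 12 in an 80 x 15 x 15 nm box with a 2 percent
#' step budget: large enough to phase separate at low temperature, small
#' enough to run in minutes.
#'
#' @param temperature Thermostat temperature, K.
#' @param seed Integer seed.
#' @param budget Step-budget factor (applied to the full-scale schedule).
#' @export
scaled_down_config <- function(temperature = 200, seed = 1, budget = 0.02) {
  # narrow initial slab (+-5 nm): the 768 beads start near the dense-phase
  # density, so the condensate forms without large-scale compaction and
  # stays slab-shaped rather than collapsing into a droplet
  simulation_config(n_polymers = 64, box = c(80, 15, 15),
                    temperature = temperature, seed = seed, budget = budget,
                    slab_half_width = 5)
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("Langevin slab simulation:\n")
  cat("  ", x$n_polymers, "polymers,",
      paste(signif(x$box, 4), collapse = " x "), "nm box, T =",
      x$temperature, "K\n")
  cat("   timestep", x$timestep, "ns (tau_v =", x$tau_v, "ns), seed",
      x$seed, "\n")
  cat("   schedule:", paste(names(x$schedule), format(x$schedule, trim = TRUE),
                            sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Initialize polymers in a slab geometry
#'
#' Places chains as confined random walks with |x - Lx/2| within the slab
#' half-width, then relaxes same-type overlaps by capped steepest descent.
#' A single dense slab nucleates one condensate with two flat interfaces
#' normal to x.
#'
#' @param spec A [polymer_spec()].
#' @param sim A [simulation_config()].
#' @param ff A [force_field()] (used for the relaxation).
#' @return A [system_configuration()] with zero velocities.
#' @export
init_slab <- function(spec, sim, ff = force_field()) {
  half <- sim$slab_half_width
  if (half > sim$box[1] / 2)
    stop("slab half-width exceeds half the box length on x")
  topo <- build_topology(spec, sim$n_polymers)
  n <- spec$n_monomers
  step_len <- 0.9 * ff$d_bead
  if (step_len >= 0.5 * ff$r0 - 0.1)
    step_len <- 0.4 * ff$r0
  cx <- sim$box[1] / 2
  pos <- with_seed(stage_seed(sim$seed, 0L), {
    out <- matrix(0, topo$n_beads, 3)
    for (p in seq_len(sim$n_polymers)) {
      start <- c(cx + runif(1, -half + 1, half - 1),
                 runif(1, 0, sim$box[2]), runif(1, 0, sim$box[3]))
      xyz <- matrix(0, n, 3)
      xyz[1, ] <- start
      for (b in 2:n) {
        repeat {
          u <- rnorm(3)
          u <- u / sqrt(sum(u^2)) * step_len
          cand <- xyz[b - 1, ] + u
          if (abs(cand[1] - cx) <= half - 0.5) break
        }
        xyz[b, ] <- cand
      }
      out[topo$chain == p, ] <- xyz
    }
    out
  })
  pos <- cpp_minimize(pos, topo$types, topo$bonds, sim$box, unclass(ff),
                      0, FALSE, 500L, 0.05)
  # relaxation has no walls; project any escapees back into the slab
  pos[, 1] <- pmin(pmax(pos[, 1], cx - half), cx + half)
  cfg <- system_configuration(pos, sim$box, topo)
  bl <- bond_lengths(cfg)
  if (any(bl > 0.5 * ff$r0))
    stop("slab initialization failed: bond longer than R0/2 after relaxation")
  cfg
}

# Minimum-image bond lengths of a configuration.
bond_lengths <- function(config) {
  b <- config$topology$bonds
  d <- config$positions[b[, 1], , drop = FALSE] -
    config$positions[b[, 2], , drop = FALSE]
  for (j in 1:3) {
    L <- config$box[j]
    d[, j] <- d[, j] - L * round(d[, j] / L)
  }
  sqrt(rowSums(d^2))
}

#' Maxwell-Boltzmann velocities
#'
#' @keywords internal
maxwell_velocities <- function(n_beads, temperature, t0, mass, seed) {
  sdv <- sqrt((temperature / t0) / mass)
  with_seed(seed, matrix(rnorm(3 * n_beads, sd = sdv), n_beads, 3))
}

#' Run Langevin dynamics
#'
#' BAOAB-split Langevin integration at the configured temperature with
#' friction `zeta = m / tau_v`, emitting trajectory frames and diagonal
#' pressure-tensor samples every `sample_every` steps.
#'
#' @param config A [system_configuration()]; if it carries no velocities
#'   they are drawn from the Maxwell-Boltzmann distribution.
#' @param ff A [force_field()].
#' @param sim A [simulation_config()].
#' @param n_steps Number of steps (default: the schedule's production
#'   steps).
#' @param u0_scale Attraction-depth scale in `[0, 1]`; a length-2 vector
#'   ramps linearly between the two values across the run.
#' @param sample_every Sampling stride (default from schedule).
#' @param save_frames Record position frames at the sampling stride.
#' @param thermostat `FALSE` runs velocity-Verlet NVE (energy-conservation
#'   diagnostics only).
#' @param wall_half If positive, reflective walls confine x to
#'   `Lx/2 +- wall_half` (slab-confinement stage).
#' @param stage Integer tag decorrelating this run's noise stream from
#'   other stages under the same seed.
#' @param t_start Time stamp of the first step, ns.
#' @return List with `trajectory` (class `trajectory`; may have zero
#'   frames if `save_frames = FALSE`), `pressure` (data.frame time_ns, px,
#'   py, pz in kB*T0/nm^3), `config` (final state with velocities),
#'   `ekin`, `epot` traces, and `aborted`.
#' @export
run_langevin <- function(config, ff, sim, n_steps = NULL, u0_scale = 1,
                         sample_every = NULL, save_frames = TRUE,
                         thermostat = TRUE, wall_half = -1, stage = 1L,
                         t_start = 0) {
  stopifnot(inherits(config, "system_configuration"),
            inherits(ff, "force_field"),
            inherits(sim, "simulation_config"))
  if (is.null(n_steps)) n_steps <- sim$schedule[["production_steps"]]
  if (is.null(sample_every)) sample_every <- sim$schedule[["sample_every"]]
  n_steps <- as.integer(n_steps)
  sample_every <- max(1L, min(as.integer(sample_every), n_steps))
  if (length(u0_scale) == 1L) u0_scale <- c(u0_scale, u0_scale)
  if (any(u0_scale < 0 | u0_scale > 1)) stop("u0_scale must lie in [0, 1]")
  vel <- config$velocities
  if (is.null(vel))
    vel <- maxwell_velocities(nrow(config$positions), sim$temperature,
                              ff$t0, sim$mass, stage_seed(sim$seed, stage))
  out <- cpp_run_langevin(config$positions, vel, config$topology$types,
                          config$topology$bonds, config$box, unclass(ff),
                          sim$temperature / ff$t0, sim$timestep, sim$tau_v,
                          sim$mass, u0_scale[1], u0_scale[2], n_steps,
                          sample_every, save_frames, thermostat, FALSE,
                          wall_half, t_start, stage_seed(sim$seed, stage + 100L))
  if (out$aborted)
    warning("run aborted at step ", out$abort_step,
            ": bond divergence or singular overlap (timestep too large?)")
  pr <- as.data.frame(out$pressure)
  names(pr) <- c("time_ns", "px", "py", "pz", "kx", "ky", "kz")
  traj <- structure(list(frames = out$frames,
                         times = as.numeric(out$frame_times),
                         box = config$box, topology = config$topology,
                         temperature = sim$temperature),
                    class = "trajectory")
  final <- system_configuration(out$positions, config$box, config$topology,
                                velocities = out$velocities)
  list(trajectory = traj, pressure = pr, config = final,
       ekin = as.numeric(out$ekin), epot = as.numeric(out$epot),
       aborted = out$aborted)
}

#' @export
print.trajectory <- function(x, ...) {
  cat("Trajectory:", length(x$frames), "frames,",
      x$topology$n_beads, "beads, box",
      paste(signif(x$box, 4), collapse = " x "), "nm\n")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj A `trajectory`.
#' @export
n_frames <- function(traj) length(traj$frames)

#' Slab equilibration protocol
#'
#' Three-stage protocol preparing a phase-separated slab: (i) relaxation
#' with the attraction off (`u0_scale = 0`) while chains are confined to
#' the slab by reflective walls; (ii) linear ramp of the attraction depth
#' from 0 to its full value; (iii) unconfined equilibration.  Stage step
#' counts come from the schedule (scaled by the configured budget).
#'
#' @param spec A [polymer_spec()].
#' @param ff A [force_field()].
#' @param sim A [simulation_config()].
#' @param config Optional starting configuration (default: [init_slab()]).
#' @return List with `config` (equilibrated state) and `report`
#'   (data.frame of stage, time_ns, ekin, epot traces).
#' @export
equilibrate_protocol <- function(spec, ff, sim, config = NULL) {
  if (is.null(config)) config <- init_slab(spec, sim, ff)
  sched <- sim$schedule
  stride <- max(1L, as.integer(sched[["sample_every"]] / 10))
  half <- sim$slab_half_width

  s1 <- run_langevin(config, ff, sim, n_steps = sched[["slab_confine_steps"]],
                     u0_scale = 0, sample_every = stride, save_frames = FALSE,
                     wall_half = half, stage = 1L)
  s2 <- run_langevin(s1$config, ff, sim, n_steps = sched[["ramp_steps"]],
                     u0_scale = c(0, 1), sample_every = stride,
                     save_frames = FALSE, wall_half = half, stage = 2L)
  s3 <- run_langevin(s2$config, ff, sim,
                     n_steps = sched[["equilibrate_steps"]],
                     u0_scale = 1, sample_every = stride, save_frames = FALSE,
                     stage = 3L)
  report <- rbind(
    data.frame(stage = "confine", time_ns = s1$pressure$time_ns,
               ekin = s1$ekin, epot = s1$epot),
    data.frame(stage = "ramp", time_ns = s2$pressure$time_ns,
               ekin = s2$ekin, epot = s2$epot),
    data.frame(stage = "equilibrate", time_ns = s3$pressure$time_ns,
               ekin = s3$ekin, epot = s3$epot))
  list(config = s3$config, report = report,
       aborted = s1$aborted || s2$aborted || s3$aborted)
}

#' Instantaneous diagonal pressure tensor of a configuration
#'
#' p_j = (sum_i m v_ij^2 + W_j) / V with W_j the minimum-image pair
#' virial.  For an ideal gas (no interactions) this reduces to the kinetic
#' term exactly.
#'
#' @param config A [system_configuration()] carrying velocities.
#' @param ff A [force_field()].
#' @param u0_scale Attraction-depth scale.
#' @return Named numeric (px, py, pz) in kB*T0/nm^3.
#' @export
pressure_tensor <- function(config, ff = force_field(), u0_scale = 1) {
  if (is.null(config$velocities))
    stop("configuration carries no velocities")
  fr <- evaluate_forces(config, ff, u0_scale)
  V <- prod(config$box)
  m <- 1
  kin <- m * colSums(config$velocities^2)
  setNames((kin + fr$virial) / V, c("px", "py", "pz"))
}

#' Kinetic temperature of a configuration
#'
#' @param config A [system_configuration()] with velocities.
#' @param t0 Reference temperature, K.
#' @return Temperature in K (equipartition: m <v^2> = 3 N kB T).
#' @export
kinetic_temperature <- function(config, t0 = 300) {
  v <- config$velocities
  if (is.null(v)) stop("no velocities")
  t0 * sum(v^2) / (3 * nrow(v))
}
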