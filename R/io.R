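#' Write a trajectory as a LAMMPS-style text dump
#'
#' Format per frame: `ITEM: TIMESTEP`, `ITEM: NUMBER OF ATOMS`,
#' `ITEM: BOX BOUNDS pp pp pp`, `ITEM: ATOMS id type x y z`.  Atom types
#' are the sticker types (1 = A, 2 = B).  Coordinates are wrapped into
#' the box on export and written with 6 decimals (nm).
#'
#' @param traj A `trajectory`.
#' @param path Output file.
#' @export
write_dump <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  types <- traj$topology$types
  for (i in seq_along(traj$frames)) {
    fr <- traj$frames[[i]]
    wrapped <- fr
    for (j in 1:3) wrapped[, j] <- fr[, j] %% traj$box[j]
    writeLines(c("ITEM: TIMESTEP", format(traj$times[i]),
                 "ITEM: NUMBER OF ATOMS", format(nrow(fr)),
                 "ITEM: BOX BOUNDS pp pp pp",
                 sprintf("0 %.6f", traj$box)), con)
    writeLines("ITEM: ATOMS id type x y z", con)
    writeLines(sprintf("%d %d %.6f %.6f %.6f", seq_len(nrow(fr)), types,
                       wrapped[, 1], wrapped[, 2], wrapped[, 3]), con)
  }
  invisible(path)
}

#' Read a LAMMPS-style text dump
#'
#' @param path Dump file written by [write_dump()] (or LAMMPS with
#'   `id type x y z` columns).
#' @param topology Optional topology restoring bonds and chains; without
#'   it atoms are read as unbonded beads of the dumped types.
#' @param unwrap Unwrap coordinates through the periodic boundaries by
#'   bond continuity (requires a topology with bonds); a note is emitted
#'   since dumps carry no image flags.
#' @return A `trajectory`.
#' @export
read_dump <- function(path, topology = NULL, unwrap = FALSE) {
  lines <- readLines(path)
  frames <- list()
  times <- numeric()
  box <- NULL
  types <- NULL
  i <- 1L
  nline <- length(lines)
  need <- function(cond, what)
    if (!cond) stop("malformed dump at line ", i, ": expected ", what)
  while (i <= nline) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    need(startsWith(lines[i], "ITEM: TIMESTEP"), "ITEM: TIMESTEP")
    need(i + 1L <= nline, "timestep value")
    tval <- as.numeric(lines[i + 1L])
    i <- i + 2L
    need(i <= nline && startsWith(lines[i], "ITEM: NUMBER OF ATOMS"),
         "ITEM: NUMBER OF ATOMS")
    nat <- as.integer(lines[i + 1L])
    need(is.finite(nat) && nat > 0, "atom count")
    i <- i + 2L
    need(i <= nline && startsWith(lines[i], "ITEM: BOX BOUNDS"),
         "ITEM: BOX BOUNDS")
    need(i + 3L <= nline, "3 box bound lines")
    bx <- vapply(1:3, function(j) {
      parts <- as.numeric(strsplit(trimws(lines[i + j]), "\\s+")[[1]])
      parts[2] - parts[1]
    }, numeric(1))
    i <- i + 4L
    need(i <= nline && startsWith(lines[i], "ITEM: ATOMS"), "ITEM: ATOMS")
    need(i + nat <= nline, paste(nat, "atom lines (file truncated?)"))
    block <- lines[(i + 1L):(i + nat)]
    m <- matrix(as.numeric(unlist(strsplit(trimws(block), "\\s+"))),
                nrow = nat, byrow = TRUE)
    need(ncol(m) >= 5 && !anyNA(m[, 1:5]), "id type x y z columns")
    ord <- order(m[, 1])
    m <- m[ord, , drop = FALSE]
    if (is.null(types)) types <- as.integer(m[, 2])
    if (is.null(box)) box <- bx
    frames[[length(frames) + 1L]] <- m[, 3:5, drop = FALSE]
    times <- c(times, tval)
    i <- i + nat + 1L
  }
  if (!length(frames)) stop("no frames found in dump")
  if (is.null(topology))
    topology <- list(types = types, bonds = matrix(integer(0), 0, 2),
                     chain = seq_along(types), n_beads = length(types))
  traj <- structure(list(frames = frames, times = times, box = box,
                         topology = topology, temperature = NA_real_),
                    class = "trajectory")
  if (unwrap) {
    if (!nrow(topology$bonds))
      stop("cannot unwrap without bond information in the topology")
    message("note: dump carries no image flags; unwrapping by bond continuity")
    traj <- unwrap_trajectory(traj)
  }
  traj
}

#' Unwrap a wrapped trajectory by bond continuity
#'
#' Rebuilds unwrapped chain coordinates by walking each chain and placing
#' every bead at the minimum-image displacement from its predecessor.
#' Valid while no bond exceeds half the smallest box length.
#'
#' @param traj A `trajectory` with chain bonds in its topology.
#' @return The trajectory with unwrapped frames.
#' @export
unwrap_trajectory <- function(traj) {
  topo <- traj$topology
  chains <- split(seq_len(topo$n_beads), topo$chain)
  box <- traj$box
  traj$frames <- lapply(traj$frames, function(fr) {
    for (idx in chains) {
      if (length(idx) < 2) next
      p <- fr[idx, , drop = FALSE]
      d <- diff(p)
      for (j in 1:3) d[, j] <- d[, j] - box[j] * round(d[, j] / box[j])
      cum <- apply(d, 2, cumsum)
      if (is.null(dim(cum))) cum <- matrix(cum, nrow = 1)
      fr[idx, ] <- rbind(p[1, , drop = FALSE], sweep(cum, 2, p[1, ], "+"))
    }
    fr
  })
  traj
}

#' Write / read trajectories in XYZ format
#'
#' Plain XYZ with element A/B per sticker type and a comment line
#' carrying the time stamp and box.
#'
#' @param traj A `trajectory`.
#' @param path File path.
#' @export
write_xyz <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  el <- c("A", "B")[traj$topology$types]
  for (i in seq_along(traj$frames)) {
    fr <- traj$frames[[i]]
    wrapped <- fr
    for (j in 1:3) wrapped[, j] <- fr[, j] %% traj$box[j]
    writeLines(format(nrow(fr)), con)
    writeLines(sprintf("time=%g box=%.6f,%.6f,%.6f", traj$times[i],
                       traj$box[1], traj$box[2], traj$box[3]), con)
    writeLines(sprintf("%s %.6f %.6f %.6f", el, wrapped[, 1], wrapped[, 2],
                       wrapped[, 3]), con)
  }
  invisible(path)
}

#' @rdname write_xyz
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  frames <- list()
  times <- numeric()
  box <- NULL
  types <- NULL
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    nat <- as.integer(lines[i])
    if (is.na(nat)) stop("malformed XYZ at line ", i)
    cm <- lines[i + 1L]
    tval <- as.numeric(sub(".*time=([-0-9.eE+]+).*", "\\1", cm))
    bx <- as.numeric(strsplit(sub(".*box=([^ ]+).*", "\\1", cm), ",")[[1]])
    if (i + 1L + nat > length(lines))
      stop("truncated XYZ frame at line ", i)
    block <- lines[(i + 2L):(i + 1L + nat)]
    parts <- strsplit(trimws(block), "\\s+")
    el <- vapply(parts, `[[`, character(1), 1)
    m <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    if (is.null(types)) types <- ifelse(el == "A", 1L, 2L)
    if (is.null(box)) box <- bx
    frames[[length(frames) + 1L]] <- m
    times <- c(times, if (is.finite(tval)) tval else length(times) + 1)
    i <- i + 2L + nat
  }
  topo <- list(types = types, bonds = matrix(integer(0), 0, 2),
               chain = seq_along(types), n_beads = length(types))
  structure(list(frames = frames, times = times, box = box,
                 topology = topo, temperature = NA_real_),
            class = "trajectory")
}

# ---------------------------------------------------------------------------
# Structured-text run configuration: INI-style sections
# [polymer] ell, n_monomers, n_polymers
# [box] lx, ly, lz
# [forcefield] k, r0, u0, eps, d, t0
# [run] temperature_k, slab_confine_steps, ramp_steps, equilibrate_steps,
#       production_steps, sample_every, seed, budget, slab_half_width
# [analysis] bin_width, rel_tol, finite_size_factor

config_known_keys <- list(
  polymer = c("ell", "n_monomers", "n_polymers"),
  box = c("lx", "ly", "lz"),
  forcefield = c("k", "r0", "u0", "eps", "d", "t0"),
  run = c("temperature_k", "slab_confine_steps", "ramp_steps",
          "equilibrate_steps", "production_steps", "sample_every", "seed",
          "budget", "slab_half_width"),
  analysis = c("bin_width", "rel_tol", "finite_size_factor"))

#' Read a run configuration file
#'
#' INI-style structured text with sections `[polymer]`, `[box]`,
#' `[forcefield]`, `[run]`, `[analysis]`.  Unknown sections or keys are
#' rejected rather than silently defaulted.
#'
#' @param path Configuration file.
#' @return List with `spec` ([polymer_spec()]), `ff` ([force_field()]),
#'   `sim` ([simulation_config()]), and `analysis` settings.
#' @export
read_sim_config <- function(path) {
  lines <- readLines(path)
  sec <- NULL
  vals <- list()
  for (ln in lines) {
    s <- trimws(sub("[#;].*$", "", ln))
    if (!nzchar(s)) next
    if (grepl("^\\[.*\\]$", s)) {
      sec <- gsub("\\[|\\]", "", s)
      if (!sec %in% names(config_known_keys))
        stop("unknown config section: [", sec, "]")
      next
    }
    if (is.null(sec)) stop("key outside any section: ", s)
    kv <- strsplit(s, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("malformed line: ", s)
    key <- trimws(kv[1])
    if (!key %in% config_known_keys[[sec]])
      stop("unknown key `", key, "` in section [", sec, "]")
    vals[[paste(sec, key, sep = ".")]] <- as.numeric(trimws(kv[2]))
  }
  g <- function(name, default = NULL) {
    if (!is.null(vals[[name]])) vals[[name]]
    else if (!is.null(default)) default
    else stop("missing config value: ", name)
  }
  spec <- polymer_spec(g("polymer.ell"), g("polymer.n_monomers"))
  ff <- force_field(k = g("forcefield.k", 0.56), r0 = g("forcefield.r0", 5),
                    u0 = g("forcefield.u0", 8), d_bead = g("forcefield.d", 1),
                    eps = g("forcefield.eps", 1), t0 = g("forcefield.t0", 300))
  sim <- simulation_config(
    n_polymers = g("polymer.n_polymers"),
    box = c(g("box.lx"), g("box.ly"), g("box.lz")),
    temperature = g("run.temperature_k"),
    seed = g("run.seed", 1),
    schedule = c(slab_confine_steps = g("run.slab_confine_steps", 1e6),
                 ramp_steps = g("run.ramp_steps", 1e6),
                 equilibrate_steps = g("run.equilibrate_steps", 1e7),
                 production_steps = g("run.production_steps", 5e7),
                 sample_every = g("run.sample_every", 1e5)),
    budget = g("run.budget", 1),
    slab_half_width = g("run.slab_half_width", 40))
  list(spec = spec, ff = ff, sim = sim,
       analysis = list(bin_width = g("analysis.bin_width", 1),
                       rel_tol = g("analysis.rel_tol", 0.10),
                       finite_size_factor = g("analysis.finite_size_factor",
                                              0.05)))
}

#' @rdname read_sim_config
#' @param cfg A list as returned by [read_sim_config()].
#' @export
write_sim_config <- function(cfg, path) {
  sim <- cfg$sim
  ff <- cfg$ff
  sp <- cfg$spec
  an <- cfg$analysis
  lines <- c(
    "[polymer]",
    sprintf("ell = %d", sp$ell),
    sprintf("n_monomers = %d", sp$n_monomers),
    sprintf("n_polymers = %d", sim$n_polymers),
    "", "[box]",
    sprintf("lx = %g", sim$box[1]), sprintf("ly = %g", sim$box[2]),
    sprintf("lz = %g", sim$box[3]),
    "", "[forcefield]",
    sprintf("k = %g", ff$k), sprintf("r0 = %g", ff$r0),
    sprintf("u0 = %g", ff$u0), sprintf("eps = %g", ff$eps),
    sprintf("d = %g", ff$d_bead), sprintf("t0 = %g", ff$t0),
    "", "[run]",
    sprintf("temperature_k = %g", sim$temperature),
    sprintf("slab_confine_steps = %g", sim$schedule[["slab_confine_steps"]]),
    sprintf("ramp_steps = %g", sim$schedule[["ramp_steps"]]),
    sprintf("equilibrate_steps = %g", sim$schedule[["equilibrate_steps"]]),
    sprintf("production_steps = %g", sim$schedule[["production_steps"]]),
    sprintf("sample_every = %g", sim$schedule[["sample_every"]]),
    sprintf("seed = %d", sim$seed),
    sprintf("slab_half_width = %g", sim$slab_half_width),
    "", "[analysis]",
    sprintf("bin_width = %g", an$bin_width),
    sprintf("rel_tol = %g", an$rel_tol),
    sprintf("finite_size_factor = %g", an$finite_size_factor))
  writeLines(lines, path)
  invisible(path)
}

#' Write a LAMMPS data file for cross-validation
#'
#' Molecular-format data file (atom types = sticker types, bonds listed
#' explicitly) so a configuration can be fed to an external MD engine.
#'
#' @param config A [system_configuration()].
#' @param path Output file.
#' @export
write_lammps_data <- function(config, path) {
  topo <- config$topology
  n <- topo$n_beads
  nb <- nrow(topo$bonds)
  pos <- config$positions
  for (j in 1:3) pos[, j] <- pos[, j] %% config$box[j]
  lines <- c("LAMMPS data file: sticker-spacer polymers", "",
             sprintf("%d atoms", n), sprintf("%d bonds", nb),
             "2 atom types", "1 bond types", "",
             sprintf("0 %.6f xlo xhi", config$box[1]),
             sprintf("0 %.6f ylo yhi", config$box[2]),
             sprintf("0 %.6f zlo zhi", config$box[3]), "",
             "Atoms # molecular", "",
             sprintf("%d %d %d %.6f %.6f %.6f", seq_len(n), topo$chain,
                     topo$types, pos[, 1], pos[, 2], pos[, 3]))
  if (nb)
    lines <- c(lines, "", "Bonds", "",
               sprintf("%d 1 %d %d", seq_len(nb), topo$bonds[, 1],
                       topo$bonds[, 2]))
  writeLines(lines, path)
  invisible(path)
}

#' Write an observables table as CSV
#'
#' Standard columns: `T_K`, `gamma`, `gamma_sem` (kB*T0/nm^2),
#' `gamma_si`, `sem_si` (N/m), `L`, `L_err`, `xi` (nm).
#'
#' @param table A data.frame from [gamma_temperature_scan()].
#' @param path Output CSV.
#' @export
write_observables_csv <- function(table, path) {
  out <- data.frame(T_K = table$temperature, gamma = table$gamma,
                    gamma_sem = table$sem,
                    gamma_si = table$gamma_si, sem_si = table$sem_si,
                    L = table$L, L_err = table$L_err, xi = table$xi)
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_observables_csv
#' @export
read_observables_csv <- function(path) {
  raw <- read.csv(path)
  data.frame(temperature = raw$T_K, gamma = raw$gamma,
             sem = raw$gamma_sem,
             gamma_si = if ("gamma_si" %in% names(raw)) raw$gamma_si else NA,
             sem_si = if ("sem_si" %in% names(raw)) raw$sem_si else NA,
             L = raw$L, L_err = raw$L_err, xi = raw$xi)
}
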