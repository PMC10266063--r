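#' @useDynLib condtension, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats coef complete.cases fft median nls predict quantile
#'   rnorm runif sd setNames var
#' @importFrom utils head read.csv tail write.csv
NULL

#' Boltzmann constant in J/K
#' @keywords internal
KB_SI <- 1.380649e-23

#' Periodic block-copolymer sticker sequence
#'
#' Builds the sticker sequence of a two-component associative polymer:
#' periodic repeats of `ell` consecutive A stickers immediately followed by
#' `ell` consecutive B stickers.  Requiring the degree of polymerization to
#' be an integer multiple of `2 * ell` enforces equal A:B stoichiometry.
#'
#' @param ell Block length (positive integer): number of consecutive
#'   stickers of one type.
#' @param n_monomers Degree of polymerization N (positive integer, multiple
#'   of `2 * ell`).
#' @return An object of class `polymer_spec`: list with `ell`, `n_monomers`,
#'   and `sequence` (character vector of "A"/"B").
#' @examples
#' polymer_spec(2, 8)$sequence   # AABBAABB
#' @export
polymer_spec <- function(ell, n_monomers) {
  ell <- as.integer(ell)
  n_monomers <- as.integer(n_monomers)
  if (length(ell) != 1L || is.na(ell) || ell < 1L)
    stop("`ell` must be a positive integer")
  if (length(n_monomers) != 1L || is.na(n_monomers) || n_monomers < 1L)
    stop("`n_monomers` must be a positive integer")
  if (n_monomers %% (2L * ell) != 0L)
    stop("stoichiometry violation: `n_monomers` (", n_monomers,
         ") must be a multiple of 2 * ell (", 2L * ell, ")")
  seq_chr <- rep(rep(c("A", "B"), each = ell), n_monomers / (2L * ell))
  structure(list(ell = ell, n_monomers = n_monomers, sequence = seq_chr),
            class = "polymer_spec")
}

#' @export
print.polymer_spec <- function(x, ...) {
  cat("Sticker polymer: N =", x$n_monomers, ", block length ell =", x$ell, "\n")
  cat("  sequence:", paste(x$sequence, collapse = ""), "\n")
  invisible(x)
}

#' Coarse-grained force field for sticker-spacer polymers
#'
#' Parameters of the three interactions: stretchable bonds between
#' consecutive beads, a short-ranged saturating A-B attraction, and a
#' purely repulsive (WCA) excluded volume between same-type beads.
#' Energies are expressed in units of kB*T0 with T0 the reference
#' temperature, so the attraction weakens in thermal units as the
#' simulation temperature rises (upper critical solution temperature).
#'
#' @param k Bond stiffness, kB*T0 / nm^2.
#' @param r0 Maximum bond extension, nm.
#' @param u0 Depth of the A-B attraction, kB*T0.
#' @param d_bead Sticker diameter, nm; also the attraction cutoff.
#' @param eps Repulsion energy scale, kB*T0.
#' @param t0 Reference temperature, K.
#' @return An object of class `force_field`.
#' @export
force_field <- function(k = 0.56, r0 = 5, u0 = 8, d_bead = 1, eps = 1,
                        t0 = 300) {
  vals <- c(k = k, r0 = r0, u0 = u0, d_bead = d_bead, eps = eps, t0 = t0)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all force-field parameters must be strictly positive and finite")
  structure(list(k = k, r0 = r0, u0 = u0, d_bead = d_bead, eps = eps,
                 t0 = t0),
            class = "force_field")
}

#' @export
print.force_field <- function(x, ...) {
  cat("Sticker-spacer force field (energies in kB*T0, lengths in nm):\n")
  cat(sprintf("  bond:       K = %.3g kB*T0/nm^2, R0 = %.3g nm\n", x$k, x$r0))
  cat(sprintf("  attraction: U0 = %.3g kB*T0, cutoff d = %.3g nm (A-B only)\n",
              x$u0, x$d_bead))
  cat(sprintf("  repulsion:  eps = %.3g kB*T0, WCA cutoff %.4g nm (same type)\n",
              x$eps, 2^(1 / 6) * x$d_bead))
  cat(sprintf("  reference temperature T0 = %.4g K\n", x$t0))
  invisible(x)
}

#' Bond energy and force
#'
#' Finitely extensible logarithmic spring between consecutive beads:
#' U(r) = -(K R0^2 / 2) log(1 - r^2/R0^2), diverging at the maximum
#' extension R0.  `bond_force` returns -dU/dr.
#'
#' @param r Separation(s), nm; must satisfy `0 <= r < r0`.
#' @param ff A [force_field()].
#' @return Energy in kB*T0 (or force in kB*T0/nm), vectorized over `r`.
#' @export
bond_energy <- function(r, ff = force_field()) {
  if (any(r < 0)) stop("negative separation")
  if (any(r >= ff$r0))
    stop("diverging bond: separation >= R0 (", ff$r0, " nm)")
  -0.5 * ff$k * ff$r0^2 * log(1 - r^2 / ff$r0^2)
}

#' @rdname bond_energy
#' @export
bond_force <- function(r, ff = force_field()) {
  if (any(r < 0)) stop("negative separation")
  if (any(r >= ff$r0))
    stop("diverging bond: separation >= R0 (", ff$r0, " nm)")
  -ff$k * r / (1 - r^2 / ff$r0^2)
}

#' Saturating A-B sticker attraction
#'
#' U(r) = -(U0/2) (1 + cos(pi r / d)) for r < d, zero beyond; continuous
#' and once-differentiable at the cutoff.  Applies to A-B pairs only;
#' bound stickers carry no mutual excluded volume and may overlap.
#'
#' @inheritParams bond_energy
#' @return Energy in kB*T0, vectorized over `r`.
#' @export
attraction_energy <- function(r, ff = force_field()) {
  if (any(r < 0)) stop("negative separation")
  ifelse(r < ff$d_bead, -0.5 * ff$u0 * (1 + cos(pi * r / ff$d_bead)), 0)
}

#' Same-type excluded volume (WCA repulsion)
#'
#' U(r) = 4 eps \[(d/r)^12 - (d/r)^6 + 1/4\] for r < 2^(1/6) d, zero beyond.
#' Applies to A-A and B-B pairs, enforcing one-to-one sticker binding.
#'
#' @inheritParams bond_energy
#' @return Energy in kB*T0, vectorized over `r`.
#' @export
repulsion_energy <- function(r, ff = force_field()) {
  if (any(r <= 0)) stop("singular overlap: separation must be > 0")
  rc <- 2^(1 / 6) * ff$d_bead
  sr6 <- (ff$d_bead / r)^6
  ifelse(r < rc, 4 * ff$eps * (sr6^2 - sr6 + 0.25), 0)
}

#' Bead topology for a set of identical polymers
#'
#' Replicates the sticker sequence of `spec` over `n_polymers` chains and
#' lists the bonds (consecutive beads within a chain).
#'
#' @param spec A [polymer_spec()].
#' @param n_polymers Number of chains.
#' @return List with `types` (integer, 1 = A, 2 = B), `bonds` (two-column
#'   integer matrix of 1-based bead indices), `chain` (chain id per bead),
#'   and `n_beads`.
#' @export
build_topology <- function(spec, n_polymers) {
  stopifnot(inherits(spec, "polymer_spec"), n_polymers >= 1)
  n <- spec$n_monomers
  types <- rep(ifelse(spec$sequence == "A", 1L, 2L), n_polymers)
  offs <- rep((seq_len(n_polymers) - 1L) * n, each = n - 1L)
  i1 <- rep(seq_len(n - 1L), n_polymers) + offs
  bonds <- cbind(i1, i1 + 1L)
  list(types = types, bonds = bonds,
       chain = rep(seq_len(n_polymers), each = n),
       n_beads = n * n_polymers)
}

#' Bead configuration in a periodic box
#'
#' @param positions Numeric matrix (n_beads x 3), nm.  Stored unwrapped;
#'   the minimum-image convention is applied when distances are needed.
#' @param box Numeric length-3, box edge lengths (Lx, Ly, Lz), nm.  The x
#'   axis is the long axis, normal to the slab interfaces.
#' @param topology A topology from [build_topology()].
#' @param velocities Optional numeric matrix (n_beads x 3), nm/ns.
#' @return Object of class `system_configuration`.
#' @export
system_configuration <- function(positions, box, topology,
                                 velocities = NULL) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 3L) stop("positions must be an n x 3 matrix")
  if (nrow(positions) != topology$n_beads)
    stop("positions and topology disagree on bead count")
  if (length(box) != 3L || any(box <= 0)) stop("box must be 3 positive lengths")
  if (!is.null(velocities)) {
    velocities <- as.matrix(velocities)
    stopifnot(all(dim(velocities) == dim(positions)))
  }
  structure(list(positions = positions, box = as.numeric(box),
                 topology = topology, velocities = velocities),
            class = "system_configuration")
}

#' @export
print.system_configuration <- function(x, ...) {
  cat("System configuration:", nrow(x$positions), "beads in a",
      paste(signif(x$box, 4), collapse = " x "), "nm periodic box\n")
  invisible(x)
}

#' Forces, potential energy, and pair virial of a configuration
#'
#' Evaluates the summed bond, attraction, and repulsion interactions under
#' the minimum-image convention, returning exact negative gradients and the
#' per-axis pair virial sums W_j = sum over pairs of r_j F_j (the
#' configurational part of the pressure tensor).
#'
#' @param config A [system_configuration()].
#' @param ff A [force_field()].
#' @param u0_scale Dimensionless factor in `[0, 1]` scaling the attraction
#'   depth (used by the equilibration ramp).
#' @param exclude_bonded If `TRUE`, nonbonded terms are not evaluated
#'   between bonded neighbours.  Default `FALSE`: same-type bonded
#'   neighbours keep their repulsion, preventing chain self-collapse.
#' @return List with `forces` (n x 3, kB*T0/nm), `energy` (kB*T0), and
#'   `virial` (length-3, kB*T0).
#' @export
evaluate_forces <- function(config, ff = force_field(), u0_scale = 1,
                            exclude_bonded = FALSE) {
  stopifnot(inherits(config, "system_configuration"))
  cpp_forces(config$positions, config$topology$types, config$topology$bonds,
             config$box, unclass(ff), u0_scale, exclude_bonded)
}
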