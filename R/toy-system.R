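#' Construct a toy dimer system
#'
#' A toy system stands in for a pair of protein monomers: a small set of
#' beads partitioned into two monomer groups ("I" and "II"), with harmonic
#' intra-monomer bonds, an attractive Lennard-Jones interface between the
#' monomers, and reference coordinates used by the structure restraints.
#'
#' Two interface modes are supported. `"axial"` (the default) applies the
#' Lennard-Jones potential to the monomer-monomer centre-of-mass distance
#' along the X axis - the same scalar used as the steering collective
#' variable - which makes the binding thermodynamics of the toy exactly
#' reducible to a one-dimensional quadrature (see
#' [exact_free_energy_1d()]). `"pair"` applies the potential to every
#' inter-monomer bead pair in full 3-D.
#'
#' @param positions Numeric n x 3 matrix of bead coordinates (Angstrom).
#' @param masses Numeric vector of bead masses (amu), all > 0.
#' @param monomer Character/factor vector of "I"/"II" labels, one per bead.
#' @param epsilon Interface Lennard-Jones well depth (kcal/mol).
#' @param sigma Interface Lennard-Jones length parameter (Angstrom).
#' @param bonds Data frame with columns `i`, `j`, `k`, `r0` (harmonic
#'   bonds, intra-monomer only); may be `NULL`.
#' @param charges Optional numeric vector of point charges (unused by the
#'   default interface modes, carried for completeness).
#' @param reference Reference coordinates for the structure restraints;
#'   defaults to `positions`.
#' @param interface `"axial"` or `"pair"` (see Details).
#'
#' @return An object of class `toy_system`.
#' @seealso [cv_com_distance_x()], [make_toy_dimer()]
#' @export
toy_system <- function(positions, masses, monomer,
                       epsilon = 3, sigma = 3,
                       bonds = NULL, charges = NULL,
                       reference = positions,
                       interface = c("axial", "pair")) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 3L)
    stop("invalid-system: 'positions' must be an n x 3 matrix")
  n <- nrow(positions)
  monomer <- as.character(monomer)
  if (length(masses) != n || length(monomer) != n)
    stop("invalid-system: masses/monomer length must match positions")
  if (any(!is.finite(masses)) || any(masses <= 0))
    stop("invalid-system: all masses must be positive")
  if (!all(monomer %in% c("I", "II")))
    stop("invalid-system: monomer labels must be 'I' or 'II'")
  if (!any(monomer == "I") || !any(monomer == "II"))
    stop("invalid-system: two non-empty monomer groups are required")
  reference <- as.matrix(reference)
  if (!all(dim(reference) == dim(positions)))
    stop("invalid-system: reference coordinates must match positions")
  if (!is.null(bonds) && nrow(bonds) > 0) {
    bonds <- as.data.frame(bonds)
    stopifnot(all(c("i", "j", "k", "r0") %in% names(bonds)))
    if (any(monomer[bonds$i] != monomer[bonds$j]))
      stop("invalid-system: bonds must stay within a monomer")
    if (any(bonds$k < 0) || any(bonds$r0 < 0))
      stop("invalid-system: bond constants must be non-negative")
  }
  if (epsilon <= 0 || sigma <= 0)
    stop("invalid-system: epsilon and sigma must be positive")
  interface <- match.arg(interface)
  structure(list(
    positions = positions, masses = as.numeric(masses), monomer = monomer,
    epsilon = epsilon, sigma = sigma,
    bonds = bonds, charges = charges,
    reference = reference, interface = interface
  ), class = "toy_system")
}

#' @export
print.toy_system <- function(x, ...) {
  cat("toy_system:", nrow(x$positions), "beads (",
      sum(x$monomer == "I"), "in monomer I,",
      sum(x$monomer == "II"), "in monomer II )\n")
  cat("  interface:", x$interface,
      sprintf("LJ(eps = %g kcal/mol, sigma = %g A)", x$epsilon, x$sigma), "\n")
  cat("  bonds:", if (is.null(x$bonds)) 0 else nrow(x$bonds), "\n")
  invisible(x)
}

# indices and normalized mass weights of one monomer group
.monomer_weights <- function(system, which) {
  idx <- which(system$monomer == which)
  w <- system$masses[idx]
  list(idx = idx, w = w / sum(w))
}

#' Mass-weighted monomer centre of mass
#'
#' @param system A [toy_system()].
#' @param which `"I"` or `"II"`.
#' @param positions Optional coordinates overriding `system$positions`.
#' @return Length-3 numeric vector (Angstrom).
#' @export
monomer_com <- function(system, which = c("I", "II"), positions = NULL) {
  which <- match.arg(which)
  mw <- .monomer_weights(system, which)
  xyz <- if (is.null(positions)) system$positions else positions
  drop(crossprod(xyz[mw$idx, , drop = FALSE], mw$w))
}

#' Collective variable: monomer COM distance along X
#'
#' The steering coordinate of the whole pipeline: the absolute difference
#' of the mass-weighted centre-of-mass X coordinates of the two monomers.
#'
#' @inheritParams monomer_com
#' @return Scalar distance (Angstrom).
#' @examples
#' sys <- make_toy_dimer(toy_dimer_spec(beads = 1))$system
#' cv_com_distance_x(sys)
#' @export
cv_com_distance_x <- function(system, positions = NULL) {
  if (!inherits(system, "toy_system"))
    stop("invalid-system: expected a toy_system")
  abs(monomer_com(system, "I", positions)[1] -
      monomer_com(system, "II", positions)[1])
}
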