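# Assembly of the absolute binding free energy from the three process
# free energies of the restrained thermodynamic cycle plus the
# standard-state and rotational-restriction corrections.

#' Measured inputs for the cycle correction terms
#'
#' @param dr_xu,dr_yu,dr_zu Min-to-max spans (Angstrom) of the
#'   monomer-monomer distance components in the restrained unbound state.
#' @param dr_yb,dr_zb Maximum absolute deviations (Angstrom) of the y/z
#'   distance components about their means in the restrained bound state.
#' @param r_b Average radial monomer-monomer distance (Angstrom) in the
#'   unrestrained bound state.
#' @param V0 Standard-state volume (A^3); 1661 A^3 corresponds to the
#'   1 mol/L standard concentration.
#' @param temperature Temperature (K).
#' @return An object of class `correction_inputs`.
#' @export
correction_inputs <- function(dr_xu, dr_yu, dr_zu, dr_yb, dr_zb, r_b,
                              V0 = 1661, temperature = 298) {
  vals <- c(dr_xu, dr_yu, dr_zu, dr_yb, dr_zb, r_b, V0)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("domain error: all spans, deviations, r_b and V0 must be positive")
  structure(list(dr_xu = dr_xu, dr_yu = dr_yu, dr_zu = dr_zu,
                 dr_yb = dr_yb, dr_zb = dr_zb, r_b = r_b,
                 V0 = V0, temperature = temperature),
            class = "correction_inputs")
}

#' Standard-state (volume) correction
#'
#' Free-energy change of transferring one molecule from the restrained
#' unbound volume `V_u = dr_xu * dr_yu * dr_zu` to the standard-state
#' volume `V0`:
#' `dF_V = kB T log( V0 / (dr_xu * dr_yu * dr_zu) )`.
#' A restrained volume smaller than `V0` gives a positive correction.
#'
#' @param inputs A [correction_inputs()].
#' @return Correction (kcal/mol).
#' @export
standard_state_correction <- function(inputs) {
  stopifnot(inherits(inputs, "correction_inputs"))
  Vu <- inputs$dr_xu * inputs$dr_yu * inputs$dr_zu
  kBT(inputs$temperature) * log(inputs$V0 / Vu)
}

#' Rotational-restriction correction
#'
#' Accounts for the relative orientational freedom suppressed by the
#' bound-state restraints: the restrained bound state explores a patch
#' `dr_yb * dr_zb` of the sphere of radius `r_b` that the unrestrained
#' monomer pair would explore,
#' `dF_R = kB T log( (dr_yb * dr_zb) / (4 pi r_b^2) )`.
#' Tight transverse restraints give a negative correction.
#'
#' @inheritParams standard_state_correction
#' @return Correction (kcal/mol).
#' @export
rotational_correction <- function(inputs) {
  stopifnot(inherits(inputs, "correction_inputs"))
  kBT(inputs$temperature) *
    log((inputs$dr_yb * inputs$dr_zb) / (4 * pi * inputs$r_b^2))
}

#' Free-energy components of the thermodynamic cycle
#'
#' @param dF_A,dF_B,dF_C Process free energies (kcal/mol): A and C are
#'   the restraint-release processes at the unbound and bound state, B
#'   the restrained virtual binding process.
#' @param s_A,s_B,s_C Their standard errors (kcal/mol), >= 0.
#' @param dF_V,dF_R Standard-state and rotational corrections (treated
#'   as exact).
#' @param temperature Temperature (K).
#' @return An object of class `cycle_components`.
#' @export
cycle_components <- function(dF_A, dF_B, dF_C, s_A = 0, s_B = 0, s_C = 0,
                             dF_V = 0, dF_R = 0, temperature = 298) {
  if (any(c(s_A, s_B, s_C) < 0))
    stop("invalid components: errors must be >= 0")
  vals <- c(dF_A, dF_B, dF_C, s_A, s_B, s_C, dF_V, dF_R)
  if (any(!is.finite(vals)))
    stop("invalid components: all fields must be finite")
  structure(list(dF_A = dF_A, dF_B = dF_B, dF_C = dF_C,
                 s_A = s_A, s_B = s_B, s_C = s_C,
                 dF_V = dF_V, dF_R = dF_R, temperature = temperature),
            class = "cycle_components")
}

#' Assemble the absolute binding free energy
#'
#' `dF = -dF_A + dF_B + dF_C + dF_V + dF_R`, with the uncertainty
#' propagated in quadrature over the three simulated processes
#' (`sigma = sqrt(s_A^2 + s_B^2 + s_C^2)`; the corrections carry no
#' error).
#'
#' @param components A [cycle_components()].
#' @return An object of class `cycle_result`: list with `dF`, `sigma`
#'   and the components.
#' @examples
#' comp <- cycle_components(dF_A = -77.88, dF_B = -25.02, dF_C = -61.66,
#'                          s_A = 0.89, s_B = 0.95, s_C = 0.53,
#'                          dF_V = 5.45, dF_R = -5.62)
#' assemble_cycle(comp)
#' @export
assemble_cycle <- function(components) {
  stopifnot(inherits(components, "cycle_components"))
  dF <- with(components, -dF_A + dF_B + dF_C + dF_V + dF_R)
  sigma <- with(components, sqrt(s_A^2 + s_B^2 + s_C^2))
  structure(list(dF = dF, sigma = sigma, components = components),
            class = "cycle_result")
}

#' @export
print.cycle_result <- function(x, ...) {
  c <- x$components
  cat("Thermodynamic-cycle binding free energy\n")
  cat(sprintf("  dF_A (unbound release) = %8.2f +/- %.2f kcal/mol\n",
              c$dF_A, c$s_A))
  cat(sprintf("  dF_B (virtual binding) = %8.2f +/- %.2f kcal/mol\n",
              c$dF_B, c$s_B))
  cat(sprintf("  dF_C (bound release)   = %8.2f +/- %.2f kcal/mol\n",
              c$dF_C, c$s_C))
  cat(sprintf("  dF_V (standard state)  = %8.2f kcal/mol\n", c$dF_V))
  cat(sprintf("  dF_R (rotational)      = %8.2f kcal/mol\n", c$dF_R))
  cat(sprintf("  dF = -dF_A + dF_B + dF_C + dF_V + dF_R = %.2f +/- %.2f kcal/mol\n",
              x$dF, x$sigma))
  cat("  (steering along a fixed axis: no Jacobian correction required)\n")
  invisible(x)
}

#' Measure correction inputs from simulated frames
#'
#' Distills the spans and deviations entering the correction terms from
#' per-frame monomer-monomer COM separation components: min-to-max spans
#' of x, y, z in the restrained unbound frames; maximum |deviation| of y
#' and z about their means in the restrained bound frames; and the mean
#' radial separation of the unrestrained bound frames (defaulting to the
#' restrained bound frames when no unrestrained run is supplied).
#'
#' @param bound_frames Matrix (frames x 3) of COM separation components
#'   from the restrained bound state (e.g. `$com_sep` of
#'   [run_equilibrium()]).
#' @param unbound_frames Same, restrained unbound state.
#' @param bound_unrestrained Optional same, unrestrained bound state
#'   (source of `r_b`).
#' @param V0,temperature Passed to [correction_inputs()].
#' @return A [correction_inputs()].
#' @export
measure_correction_inputs <- function(bound_frames, unbound_frames,
                                      bound_unrestrained = NULL,
                                      V0 = 1661, temperature = 298) {
  bound_frames <- as.matrix(bound_frames)
  unbound_frames <- as.matrix(unbound_frames)
  if (nrow(bound_frames) < 2L || nrow(unbound_frames) < 2L)
    stop("degenerate-span error: need at least 2 frames per state")
  span <- function(v) diff(range(v))
  maxdev <- function(v) max(abs(v - mean(v)))
  if (is.null(bound_unrestrained)) bound_unrestrained <- bound_frames
  bu <- as.matrix(bound_unrestrained)
  r_b <- mean(sqrt(rowSums(bu^2)))
  correction_inputs(
    dr_xu = span(unbound_frames[, 1]),
    dr_yu = span(unbound_frames[, 2]),
    dr_zu = span(unbound_frames[, 3]),
    dr_yb = maxdev(bound_frames[, 2]),
    dr_zb = maxdev(bound_frames[, 3]),
    r_b = r_b, V0 = V0, temperature = temperature
  )
}
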