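# Unit system used throughout: kcal/mol (energy), Angstrom (length),
# ps (time), amu (mass), Kelvin (temperature).

#' Physical constants of the package unit system
#'
#' Boltzmann constant in kcal mol^-1 K^-1 and the acceleration conversion
#' factor turning (kcal mol^-1 A^-1)/amu into A ps^-2.
#'
#' @format `kB` and `acc_conv` are length-one numerics.
#' @name constants
#' @keywords internal
NULL

# Boltzmann constant, kcal mol^-1 K^-1
.kB <- 0.0019872

# 1 (kcal/mol/A)/amu = 418.4 A/ps^2  (4184 J per kcal)
.ACC <- 418.4

#' Thermal energy k_B T
#'
#' @param temperature Temperature in Kelvin.
#' @return Thermal energy in kcal mol^-1.
#' @examples
#' kBT(298) # ~0.592 kcal/mol
#' @export
kBT <- function(temperature) {
  stopifnot(is.numeric(temperature), temperature >= 0)
  .kB * temperature
}

# Bondi van-der-Waals radii (Angstrom) used by the SASA engine.
# Elements outside this table raise an error naming the atom.
.BONDI <- c(
  H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80,
  P = 1.80, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98,
  SE = 1.90, ZN = 1.39, "NA" = 2.27, K = 2.75, MG = 1.73, CA = 2.31
)

#' van der Waals radii table
#'
#' The Bondi radii (in Angstrom) used by [sasa()]. Returned as a named
#' numeric vector keyed by upper-case element symbol.
#'
#' @return Named numeric vector of radii.
#' @export
vdw_radii <- function() .BONDI
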