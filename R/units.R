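#' Physical constants and unit helpers
#'
#' Internal energies are kept in kcal/mol and distances in Angstrom; the
#' toy sampler works in kT-reduced units and PLUMED-style files carry
#' kJ/mol. Conversions happen only at those boundaries, with the exact
#' thermochemical calorie (4.184 J/cal).
#'
#' @name hjdyn-units
#' @keywords internal
NULL

# Boltzmann constant, kcal/mol/K
.KB_KCAL <- 0.0019872041
# kcal <-> kJ, exact by definition
.KCAL_TO_KJ <- 4.184
# molarity of pure water used for concentration conversion, mol/L
.WATER_MOLARITY <- 55.34
# Avogadro constant, 1/mol
.N_AVOGADRO <- 6.02214076e23

#' Thermal energy at a given temperature
#'
#' @param T_K temperature in Kelvin (default 298.15).
#' @param unit `"kcal"` or `"kJ"` per mol.
#' @return kT in the requested unit. At 298.15 K this is 0.593 kcal/mol
#'   (2.479 kJ/mol).
#' @examples
#' kT(298.15)            # 0.5925 kcal/mol
#' kT(298.15, "kJ")      # 2.479 kJ/mol
#' @export
kT <- function(T_K = 298.15, unit = c("kcal", "kJ")) {
  unit <- match.arg(unit)
  stopifnot(is.numeric(T_K), T_K > 0)
  kt <- .KB_KCAL * T_K
  if (unit == "kJ") kt <- kt * .KCAL_TO_KJ
  kt
}

#' @rdname kT
#' @export
kcal_to_kj <- function(x) x * .KCAL_TO_KJ

#' @rdname kT
#' @export
kj_to_kcal <- function(x) x / .KCAL_TO_KJ
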