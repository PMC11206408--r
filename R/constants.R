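#' Physical constants and unit conventions
#'
#' All coordinates are in angstrom, times in picoseconds, energies in
#' kcal mol^-1 and charges in elementary-charge units. Temperatures are in
#' kelvin with a package-wide default of 310.15 K (physiological).
#'
#' @format `spla2_constants` is a named list with elements:
#' \describe{
#'   \item{R_kcal}{Gas constant, kcal mol^-1 K^-1 (1.987204e-3).}
#'   \item{kB_J}{Boltzmann constant, J K^-1 (CODATA 2018).}
#'   \item{h_J}{Planck constant, J s (CODATA 2018).}
#'   \item{coulomb_kcal}{Coulomb prefactor, kcal A mol^-1 e^-2 (332.0637).}
#'   \item{temperature_K}{Default temperature, K.}
#' }
#' @export
spla2_constants <- list(
  R_kcal        = 1.987204e-3,
  kB_J          = 1.380649e-23,
  h_J           = 6.62607015e-34,
  coulomb_kcal  = 332.0637,
  temperature_K = 310.15
)

#' Thermal energy RT in kcal mol^-1
#'
#' @param temperature Temperature in kelvin.
#' @return RT in kcal mol^-1.
#' @examples
#' rt_kcal()          # 0.61633 at 310.15 K
#' @export
rt_kcal <- function(temperature = spla2_constants$temperature_K) {
  stopifnot(is.numeric(temperature), temperature > 0)
  spla2_constants$R_kcal * temperature
}

# Bondi van der Waals radii (A), element-keyed; Ca from the common extension
# of the Bondi set. Overridable via the `radii` argument of sasa().
bondi_radii <- c(
  H = 1.20, C = 1.70, N = 1.55, O = 1.52, P = 1.80, S = 1.80,
  F = 1.47, Cl = 1.75, Br = 1.85, I = 1.98, Na = 2.27, K = 2.75,
  Mg = 1.73, Ca = 2.31, Zn = 1.39
)
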