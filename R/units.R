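#' Physical constants and unit helpers
#'
#' The engine itself is unit-agnostic: energies, lengths and times are
#' whatever the potential terms and time step imply, and the `temperature`
#' given to [engine_params()] is a *thermal energy* (kB·T). In reduced mode
#' (the default for toy systems) kB = 1 so the thermal energy equals the
#' dimensionless temperature. In physical mode (kcal/mol, Angstrom) use
#' [thermal_energy()] to convert a temperature in kelvin.
#'
#' @param temperature_K temperature in kelvin.
#' @return thermal energy kB·T in kcal/mol.
#' @examples
#' thermal_energy(310.15) # ~0.616 kcal/mol
#' @export
thermal_energy <- function(temperature_K) {
  stopifnot(is.numeric(temperature_K), temperature_K >= 0)
  .kB_kcal * temperature_K
}

# Boltzmann constant in kcal/mol/K and Avogadro's number
.kB_kcal <- 0.0019872041
.avogadro <- 6.02214076e23
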