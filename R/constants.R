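# CODATA 2018 values, SI units unless noted
.const <- list(
  e        = 1.602176634e-19,   # elementary charge, C
  eps0     = 8.8541878128e-12,  # vacuum permittivity, F m^-1
  kB       = 1.380649e-23,      # Boltzmann constant, J K^-1
  N_A      = 6.02214076e23,     # Avogadro constant, mol^-1
  R        = 8.314462618,       # gas constant, J mol^-1 K^-1
  r0_cm    = 0.28179e-12,       # classical electron radius, cm e^-1
  ang      = 1e-10              # 1 Angstrom in m
)

#' Extended palmitoyl (C16) chain length
#'
#' Reference length of a fully extended hexadecyl chain, 17.6 Angstrom,
#' kept as a documented constant for comparison with fitted micelle core
#' radii (fitted cores shorter than this indicate chain disorder or
#' partial incorporation of the chain in the shell). No formula for it is
#' computed by the package.
#'
#' @format A single numeric value (Angstrom).
#' @export
c16_extended_length <- 17.6

#' Relative permittivity of pure water
#'
#' Empirical static dielectric constant of liquid water as a function of
#' temperature (Malmberg-Maryott polynomial in degrees Celsius). Returns
#' 80.1 at 293 K, the default solvent permittivity used throughout the
#' package.
#'
#' @param temperature Temperature in kelvin.
#' @return Dimensionless relative permittivity.
#' @examples
#' water_permittivity(293)
#' @export
water_permittivity <- function(temperature = 293) {
  stopifnot(is.numeric(temperature), all(temperature > 273), all(temperature < 373))
  t <- temperature - 273.15
  87.740 - 0.40008 * t + 9.398e-4 * t^2 - 1.410e-6 * t^3
}
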