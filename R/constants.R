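#' Physical constants used throughout the package
#'
#' The gas constant is carried in calorie units so that enthalpies in
#' kcal/mol and entropies in cal/(mol K) combine without unit juggling;
#' all equilibrium expressions evaluate temperatures in Kelvin and
#' reporting converts back to degrees Celsius.
#'
#' @return Named list with `R` (gas constant, 1.987 cal mol-1 K-1),
#'   `T_ref` (reference temperature for Gibbs energies, 298.15 K) and
#'   `zero_C` (0 degrees Celsius in Kelvin, 273.15).
#' @export
#' @examples
#' thermo_constants()$R
thermo_constants <- function() {
  list(R = 1.987, T_ref = 298.15, zero_C = 273.15)
}

# internal shorthands
.R_GAS <- 1.987
.T_REF <- 298.15
.ZERO_C <- 273.15

celsius_to_kelvin <- function(x) x + .ZERO_C
kelvin_to_celsius <- function(x) x - .ZERO_C
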