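#' Physical constants for folding thermodynamics
#'
#' All free energies in this package are in kcal/mol and all m-values in
#' kcal/mol/M, so the gas constant is carried in kcal/(mol K). Experiments
#' are assumed isothermal at 25 C (298 K) unless a different temperature is
#' supplied.
#'
#' @param temperature Temperature in kelvin. Default 298.
#' @return A list with components `R` (gas constant, kcal/(mol K)),
#'   `T` (kelvin) and `RT` (their product, kcal/mol).
#' @examples
#' folding_constants()$RT  # ~0.5918 kcal/mol
#' @export
folding_constants <- function(temperature = 298) {
  stopifnot(is.numeric(temperature), length(temperature) == 1L, temperature > 0)
  R <- 1.986e-3
  list(R = R, T = temperature, RT = R * temperature)
}

# Shared default: RT at 298 K, kcal/mol. Used as the default `rt` argument
# throughout so every equation is overridable but consistent.
.RT <- 1.986e-3 * 298
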