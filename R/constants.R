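#' Physical constants for electrodiffusion calculations
#'
#' Bundles the constants entering the Woodhull block model, the Boltzmann
#' surface-potential relations and the screened-Coulomb (Debye-Hueckel)
#' potential: Faraday constant, gas constant, vacuum and relative
#' permittivity, and the thermal voltage `RT/F`.
#'
#' At the default 298.15 K, `RT_over_F_mV` is 25.69 mV, the value implied by
#' the 180 mV/Angstrom screened-Coulomb prefactor used throughout the
#' electrostatics helpers.
#'
#' @param temperature_K Absolute temperature in kelvin.
#' @param epsilon Relative permittivity of the electrolyte (water: 78.5).
#' @return An object of class `physical_constants`: a list with fields
#'   `F` (C/mol), `R` (J/mol/K), `temperature_K`, `RT_over_F_mV` (mV),
#'   `epsilon0` (F/m) and `epsilon` (dimensionless).
#' @examples
#' physical_constants()$RT_over_F_mV  # ~25.7 mV
#' @export
physical_constants <- function(temperature_K = 298.15, epsilon = 78.5) {
  stopifnot(temperature_K > 0, epsilon > 0)
  faraday <- 96485.33212   # C/mol
  gas_r <- 8.314462618     # J/mol/K
  out <- list(
    F = faraday,
    R = gas_r,
    temperature_K = temperature_K,
    RT_over_F_mV = 1000 * gas_r * temperature_K / faraday,
    epsilon0 = 8.8541878128e-12,
    epsilon = epsilon
  )
  class(out) <- "physical_constants"
  out
}

# Run an expression under a private, seeded RNG stream, restoring the caller's
# RNG state afterwards. All stochastic generator code funnels through this so
# that (fixture, protocol, seed) fully determines a simulated trace.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}
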