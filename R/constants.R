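# Physical constants, defined once for the whole package.
#
# .const$R_kcal is the gas constant in kcal/(mol K) and is the value used in
# every van 't Hoff / Arrhenius expression (enthalpies in kcal/mol).
# .const$kB_mV is kB/e in mV/K, so that z*V_mV/(kB_mV*T) is dimensionless.
.const <- list(
  R_kcal  = 1.9872e-3,   # kcal/(mol K)
  R_J     = 8.31446,     # J/(mol K)
  F_C     = 96485.332,   # C/mol
  kB_mV   = 8.6173332e-2 # mV/K (Boltzmann constant over elementary charge)
)

#' Physical constants used by the package
#'
#' Returns the single authoritative set of physical constants used in all
#' thermodynamic expressions: the gas constant in kcal/(mol K) (enthalpies are
#' in kcal/mol throughout), the gas constant in J/(mol K), Faraday's constant,
#' and the Boltzmann constant expressed in mV/K so that voltage terms
#' \eqn{z\delta V / k_B T} are dimensionless with voltages in mV.
#'
#' @return Named list with elements `R_kcal`, `R_J`, `F_C`, `kB_mV`.
#' @export
#' @examples
#' physical_constants()$R_kcal
physical_constants <- function() .const

#' Temperature unit conversion
#'
#' @param T_C temperature in degrees Celsius.
#' @param T_K temperature in kelvin.
#' @return Temperature in kelvin (`celsius_to_kelvin`) or Celsius
#'   (`kelvin_to_celsius`).
#' @export
#' @examples
#' celsius_to_kelvin(22)   # 295.15
celsius_to_kelvin <- function(T_C) T_C + 273.15

#' @rdname celsius_to_kelvin
#' @export
kelvin_to_celsius <- function(T_K) T_K - 273.15

# internal: positive-scalar validation
.check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop(sprintf("`%s` must be a single finite positive number", name),
         call. = FALSE)
  invisible(x)
}

.check_nonneg <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0))
    stop(sprintf("`%s` must be finite and non-negative", name), call. = FALSE)
  invisible(x)
}
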