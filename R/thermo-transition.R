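#' Two-state thermodynamic transition
#'
#' Describes a temperature-dependent conformational equilibrium through its
#' standard enthalpy and entropy changes, with an optional heat-capacity term.
#' The equilibrium constant is the van 't Hoff form
#' \deqn{J(T) = \exp(-(\Delta H^0 - T \Delta S^0)/RT)}
#' when `dCp = 0`, and the heat-capacity form
#' \deqn{J(T) = \exp\left(\frac{\Delta S^0(T_0)}{R} -
#'   \frac{\Delta C_p}{R}\left(1 - \frac{T_0}{T} +
#'   \ln\frac{T_0}{T}\right)\right)}
#' when `dCp != 0`, where \eqn{\Delta S^0(T_0)} is the entropy change at the
#' reference temperature `T0`.
#'
#' @param dH0 standard enthalpy change, kcal/mol. For the heat-capacity form
#'   this argument is ignored (the enthalpy change is zero at `T0` by
#'   construction of that parameterization).
#' @param dS0 standard entropy change, kcal/(mol K); for `dCp != 0` this is the
#'   entropy change at the reference temperature `T0`.
#' @param dCp heat capacity change, kcal/(mol K). Default 0 (plain van 't Hoff).
#' @param T0 reference temperature in kelvin; required when `dCp != 0`.
#' @return An object of class `thermo_transition`.
#' @seealso [equilibrium_constant()]
#' @export
#' @examples
#' J1 <- thermo_transition(dH0 = 45, dS0 = 0.133)
#' equilibrium_constant(J1, 310)
thermo_transition <- function(dH0, dS0, dCp = 0, T0 = NULL) {
  stopifnot(is.numeric(dH0), is.numeric(dS0), is.numeric(dCp))
  if (dCp != 0) {
    if (is.null(T0)) stop("`T0` is required when `dCp` is non-zero", call. = FALSE)
    .check_positive(T0, "T0")
  }
  structure(list(dH0 = dH0, dS0 = dS0, dCp = dCp, T0 = T0),
            class = "thermo_transition")
}

#' Equilibrium constant of a thermodynamic transition
#'
#' Evaluates \eqn{J(T)} for a [thermo_transition()]. Always strictly positive;
#' with `dCp = 0`, \eqn{\ln J} is affine in \eqn{1/T}.
#'
#' @param tr a [thermo_transition()].
#' @param temp temperature(s) in kelvin; must be positive.
#' @return Numeric vector of equilibrium constants, same length as `temp`.
#' @export
#' @examples
#' equilibrium_constant(thermo_transition(0, 0), 300)  # 1
equilibrium_constant <- function(tr, temp) {
  stopifnot(inherits(tr, "thermo_transition"))
  if (any(!is.finite(temp)) || any(temp <= 0))
    stop("temperature must be positive (kelvin)", call. = FALSE)
  R <- .const$R_kcal
  if (tr$dCp == 0) {
    exp(-(tr$dH0 - temp * tr$dS0) / (R * temp))
  } else {
    T0 <- tr$T0
    exp(tr$dS0 / R - (tr$dCp / R) * (1 - T0 / temp + log(T0 / temp)))
  }
}

#' @export
print.thermo_transition <- function(x, ...) {
  if (x$dCp == 0) {
    cat(sprintf(
      "<thermo_transition> dH0 = %g kcal/mol, dS0 = %g kcal/(mol K)",
      x$dH0, x$dS0))
    if (x$dS0 != 0)
      cat(sprintf(", midpoint %.1f K", x$dH0 / x$dS0))
    cat("\n")
  } else {
    cat(sprintf(
      "<thermo_transition> dS0(T0) = %g kcal/(mol K), dCp = %g kcal/(mol K), T0 = %g K\n",
      x$dS0, x$dCp, x$T0))
  }
  invisible(x)
}

#' Fit a van 't Hoff transition to tabulated equilibrium constants
#'
#' Ordinary least squares of \eqn{\ln J} against \eqn{1/T}: the slope gives
#' \eqn{-\Delta H^0/R} and the intercept \eqn{\Delta S^0/R}. Used e.g. to find
#' the van 't Hoff parameterization that matches a heat-capacity transition
#' over a temperature window.
#'
#' @param temp temperatures, kelvin.
#' @param J equilibrium constants (positive).
#' @return A [thermo_transition()] with `dCp = 0`.
#' @export
fit_vanthoff <- function(temp, J) {
  stopifnot(length(temp) == length(J), length(temp) >= 2)
  if (any(J <= 0)) stop("equilibrium constants must be positive", call. = FALSE)
  R <- .const$R_kcal
  fit <- stats::lm(log(J) ~ I(1 / temp))
  b <- stats::coef(fit)
  thermo_transition(dH0 = -unname(b[2]) * R, dS0 = unname(b[1]) * R)
}
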