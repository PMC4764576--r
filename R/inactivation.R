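#' Parameters of temperature-dependent irreversible inactivation
#'
#' Empirical description of the irreversible loss of heat-activated channels
#' during slow heating ramps: a first-order rate
#' \deqn{k(T) = k_0 \, e^{-(\Delta H^{\ne} - T\Delta S^{\ne})/RT}, \qquad
#'   k_0(T, [\mathrm{Na}^+]) = A (1 - F_{Na})^2,}
#' where \eqn{F_{Na}} is the equilibrium fraction of Na+-bound states of the
#' gating model (external Na+ protects against inactivation), applied to the
#' equilibrium open probability as a survival factor
#' \eqn{P_{o,inact}(t, T) = P_o(T) e^{-k(T) t}}.
#' The canonical constants are `A = 200`, `dH_act = 45` kcal/mol,
#' `dS_act = 0.133` kcal/(mol K), `Tmax = 333` K.
#'
#' @param A dimensionless pre-factor constant (>= 0). Default 200.
#' @param dH_act activation enthalpy, kcal/mol. Default 45.
#' @param dS_act activation entropy, kcal/(mol K). Default 0.133.
#' @param Tmax maximal ramp temperature, kelvin. Default 333.
#' @return Object of class `inactivation_params`.
#' @export
inactivation_params <- function(A = 200, dH_act = 45, dS_act = 0.133,
                                Tmax = 333) {
  .check_nonneg(A, "A"); .check_positive(Tmax, "Tmax")
  structure(list(A = A, dH_act = dH_act, dS_act = dS_act, Tmax = Tmax),
            class = "inactivation_params")
}

#' Inactivation rate constant
#'
#' @param p an [inactivation_params()].
#' @param temp temperature(s), kelvin.
#' @param F_Na equilibrium fraction of Na+-bound states, in \[0, 1\]
#'   (see [fraction_na_bound()]); `F_Na = 1` abolishes inactivation.
#' @return Rate constant(s), reciprocal ramp-clock time units.
#' @export
#' @examples
#' inactivation_rate(inactivation_params(), temp = 320, F_Na = 0)
inactivation_rate <- function(p, temp, F_Na = 0) {
  stopifnot(inherits(p, "inactivation_params"))
  if (any(F_Na < 0) || any(F_Na > 1))
    stop("`F_Na` must be in [0, 1]", call. = FALSE)
  .check_positive(min(temp), "temp")
  R <- .const$R_kcal
  p$A * (1 - F_Na)^2 * exp(-(p$dH_act - temp * p$dS_act) / (R * temp))
}

#' Sigmoidal ramp time from temperature
#'
#' Empirical transform mapping the temperature axis of a slow heating ramp
#' back onto ramp time, derived from the sigmoidal shape of experimental
#' temperature-versus-time records:
#' \deqn{t(T) = -0.83258 \,\ln\!\left(\frac{T_{max}}{T - 0.1} - 1\right)
#'   + 3.3181,}
#' strictly increasing on its domain, with \eqn{T \to T_{max}} as
#' \eqn{t \to \infty}. Times are in the ramp-clock units implied by the
#' transform; only relative times matter to the survival product.
#'
#' @param p an [inactivation_params()] (provides `Tmax`).
#' @param temp temperature(s), kelvin; must satisfy
#'   `0.1 < temp < Tmax + 0.1`.
#' @return Ramp time(s).
#' @export
ramp_time_from_temperature <- function(p, temp) {
  stopifnot(inherits(p, "inactivation_params"))
  arg <- p$Tmax / (temp - 0.1) - 1
  if (any(!is.finite(arg)) || any(arg <= 0))
    stop(sprintf(
      "temperature outside the transform domain (0.1, %.1f) K", p$Tmax + 0.1),
      call. = FALSE)
  -0.83258 * log(arg) + 3.3181
}

#' Inverse of the ramp time-transform
#'
#' Temperature reached at ramp time `t`:
#' \eqn{T(t) = 0.1 + T_{max} / (1 + e^{-(t - 3.3181)/0.83258})}.
#'
#' @param p an [inactivation_params()].
#' @param t ramp time(s).
#' @return Temperature(s), kelvin.
#' @export
ramp_temperature_from_time <- function(p, t) {
  stopifnot(inherits(p, "inactivation_params"))
  0.1 + p$Tmax / (1 + exp(-(t - 3.3181) / 0.83258))
}

#' Overlay irreversible inactivation on an equilibrium Po-T relation
#'
#' At each point of a heating-ramp open-probability-temperature relation,
#' computes the Na+-bound fraction from the gating model, the ramp time from
#' the sigmoidal time-transform, and multiplies the equilibrium open
#' probability by the survival factor \eqn{e^{-k(T) t}}. The default follows
#' the pointwise instantaneous-time recipe; `cumulative = TRUE` instead uses
#' the cumulative hazard \eqn{\exp(-\int k\, dt)} over the ramp history
#' (a non-canonical variant retained for comparison).
#'
#' @param pot a [pot_relation()] on a monotone-increasing temperature grid.
#' @param p an [inactivation_params()].
#' @param model the [allosteric_model()] supplying \eqn{F_{Na}}.
#' @param na external Na+ concentration, molar.
#' @param caps capsaicin concentration, molar.
#' @param time_scale multiplies all ramp times (a fast ramp has
#'   `time_scale` close to 0, making the overlay vanish). Default 1.
#' @param cumulative use the cumulative-hazard variant. Default `FALSE`.
#' @return A [pot_relation()] with `Po` attenuated pointwise
#'   (output <= input everywhere).
#' @export
apply_inactivation <- function(pot, p, model, na = 0, caps = 0,
                               time_scale = 1, cumulative = FALSE) {
  stopifnot(inherits(pot, "pot_relation"), inherits(p, "inactivation_params"),
            inherits(model, "allosteric_model"))
  if (is.unsorted(pot$T_K, strictly = FALSE))
    stop("`pot` must be on a monotone-increasing temperature grid", call. = FALSE)
  F_Na <- fraction_na_bound(model, pot$T_K, na = na, caps = caps)
  k <- inactivation_rate(p, pot$T_K, F_Na)
  t <- ramp_time_from_temperature(p, pot$T_K) * time_scale
  if (cumulative) {
    # trapezoidal cumulative hazard over the ramp history
    dt <- diff(t)
    haz <- cumsum(c(0, (k[-1] + k[-length(k)]) / 2 * dt))
    surv <- exp(-haz)
  } else {
    surv <- exp(-k * t)
  }
  pot_relation(pot$T_K, pot$Po * surv,
               sem = if ("sem" %in% names(pot)) pot$sem * surv,
               scale_ref = attr(pot, "scale_ref"))
}
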