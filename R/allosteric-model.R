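#' Allosteric gating model with two sequential temperature sensors
#'
#' Constructs the main allosteric equilibrium model of channel gating
#' ("model i"): a temperature-independent pore opening equilibrium `L` coupled
#' to a two-step temperature sensor (sequential equilibria `J1`, `J2`), to
#' external Na+ binding, and optionally to capsaicin binding.
#'
#' State weights relative to the reference state (pore closed, sensor resting,
#' unliganded) are built multiplicatively:
#' \itemize{
#'   \item sensor step 1 contributes \eqn{J_1(T)}; step 2 contributes
#'     \eqn{J_1(T) J_2(T)} (sequential arrangement);
#'   \item the open pore contributes \eqn{L}, multiplied by the coupling
#'     factor \eqn{D} once the sensor has left the resting state and by
#'     \eqn{D E} when fully activated;
#'   \item Na+-bound states carry the cooperative binding term
#'     \eqn{(K_1' [\mathrm{Na}])^{n}} (Hill-style exponent `coop`, default 1.5)
#'     and the coupling factors \eqn{G} (sensor at step >= 1), \eqn{H}
#'     (step 2) and \eqn{F} (pore open);
#'   \item capsaicin-bound states carry \eqn{(K_2' [\mathrm{caps}])^{n}} and
#'     generic coupling factors `c_L` (pore open), `c_J1`, `c_J2`
#'     (sensor steps) and `c_Na` (interaction with Na+ binding).
#' }
#' Inhibition by Na+ corresponds to `F`, `G`, `H` < 1; sensor-to-pore coupling
#' to `D`, `E` > 1. With every coupling factor equal to 1 the open probability
#' is `L/(1+L)` independently of temperature and ligands.
#'
#' @param L intrinsic (sensor-resting, unliganded) opening equilibrium
#'   constant, dimensionless.
#' @param J1,J2 [thermo_transition()] objects for the first and second
#'   temperature-dependent sensor steps.
#' @param D,E coupling factors of sensor steps 1 and 2 to pore opening.
#' @param K1 Na+ association constant \eqn{K_1'}, per molar.
#' @param F_na,G,H coupling factors of Na+ binding to the opening equilibrium
#'   and to sensor steps 1 and 2.
#' @param K2 capsaicin association constant \eqn{K_2'}, per molar, or `NULL`
#'   for a model without the capsaicin extension.
#' @param caps named list of capsaicin coupling factors `c_L`, `c_J1`, `c_J2`,
#'   `c_Na`; missing entries default to 1 (neutral).
#' @param coop Hill-style cooperativity exponent applied to both binding
#'   terms. Default 1.5.
#' @return Object of class `allosteric_model`.
#' @seealso [open_probability()], [enumerate_states()], [fraction_na_bound()]
#' @export
#' @examples
#' m <- allosteric_model(
#'   L = 0.005,
#'   J1 = thermo_transition(30, 30 / 275),
#'   J2 = thermo_transition(100, 100 / 315),
#'   D = 50, E = 600, K1 = 1 / 0.007, F_na = 0.2, G = 0.01, H = 0.5)
#' open_probability(m, temp = seq(280, 320, 5), na = 0.13)
allosteric_model <- function(L, J1, J2, D = 1, E = 1,
                             K1 = 1, F_na = 1, G = 1, H = 1,
                             K2 = NULL, caps = list(), coop = 1.5) {
  stopifnot(inherits(J1, "thermo_transition"), inherits(J2, "thermo_transition"))
  for (nm in c("L", "D", "E", "K1", "F_na", "G", "H", "coop"))
    .check_positive(get(nm), nm)
  if (!is.null(K2)) .check_positive(K2, "K2")
  caps_def <- list(c_L = 1, c_J1 = 1, c_J2 = 1, c_Na = 1)
  unknown <- setdiff(names(caps), names(caps_def))
  if (length(unknown))
    stop("unknown capsaicin coupling factor(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  caps_def[names(caps)] <- caps
  for (nm in names(caps_def)) .check_positive(caps_def[[nm]], nm)
  structure(
    list(L = L, J1 = J1, J2 = J2, D = D, E = E,
         K1 = K1, F_na = F_na, G = G, H = H,
         K2 = K2, caps = caps_def, coop = coop),
    class = "allosteric_model")
}

#' @export
print.allosteric_model <- function(x, ...) {
  cat("<allosteric_model> two sequential temperature sensors\n")
  cat(sprintf("  L = %g; D = %g, E = %g\n", x$L, x$D, x$E))
  cat(sprintf("  Na+ binding: K1' = %g /M, F = %g, G = %g, H = %g (coop %g)\n",
              x$K1, x$F_na, x$G, x$H, x$coop))
  if (!is.null(x$K2))
    cat(sprintf("  capsaicin: K2' = %g /M, c_L = %g, c_J1 = %g, c_J2 = %g, c_Na = %g\n",
                x$K2, x$caps$c_L, x$caps$c_J1, x$caps$c_J2, x$caps$c_Na))
  invisible(x)
}

# cooperative binding term (K' [ligand])^coop, with 0^coop = 0
.binding_term <- function(K, conc, coop) {
  if (is.null(K) || conc <= 0) return(0)
  (K * conc)^coop
}

#' Enumerate the states of an allosteric gating model
#'
#' Explicit brute-force enumeration of the state space of an
#' [allosteric_model()] at one condition: 3 sensor positions x 2 pore states
#' x 2 Na+-occupancy states (x 2 capsaicin-occupancy states when the model
#' carries the capsaicin extension), each with its statistical weight relative
#' to the reference state. This enumeration is the ground-truth oracle for the
#' closed-form [open_probability()].
#'
#' @param model an [allosteric_model()].
#' @param temp temperature, kelvin (scalar).
#' @param na external Na+ concentration, molar.
#' @param caps capsaicin concentration, molar.
#' @return `data.frame` with columns `sensor_step` (0, 1, 2), `pore`
#'   ("closed"/"open"), `na_bound`, `caps_bound` (logical) and `weight`.
#' @export
enumerate_states <- function(model, temp, na = 0, caps = 0) {
  stopifnot(inherits(model, "allosteric_model"), length(temp) == 1L)
  .check_nonneg(na, "na"); .check_nonneg(caps, "caps")
  J1 <- equilibrium_constant(model$J1, temp)
  J2 <- equilibrium_constant(model$J2, temp)
  Kna <- .binding_term(model$K1, na, model$coop)
  Kc  <- .binding_term(model$K2, caps, model$coop)
  has_caps <- !is.null(model$K2)
  caps_states <- if (has_caps) c(FALSE, TRUE) else FALSE

  grid <- expand.grid(sensor_step = 0:2, pore = c("closed", "open"),
                      na_bound = c(FALSE, TRUE), caps_bound = caps_states,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  w <- numeric(nrow(grid))
  for (k in seq_len(nrow(grid))) {
    s <- grid$sensor_step[k]
    open <- grid$pore[k] == "open"
    wk <- c(1, J1, J1 * J2)[s + 1]
    if (open) wk <- wk * model$L * ifelse(s >= 1, model$D, 1) *
        ifelse(s == 2, model$E, 1)
    if (grid$na_bound[k])
      wk <- wk * Kna * ifelse(s >= 1, model$G, 1) *
        ifelse(s == 2, model$H, 1) * ifelse(open, model$F_na, 1)
    if (grid$caps_bound[k])
      wk <- wk * Kc * ifelse(open, model$caps$c_L, 1) *
        ifelse(s >= 1, model$caps$c_J1, 1) * ifelse(s == 2, model$caps$c_J2, 1) *
        ifelse(grid$na_bound[k], model$caps$c_Na, 1)
    w[k] <- wk
  }
  grid$weight <- w
  grid
}

# closed-form partition sums for model i; vectorized over temp.
# Returns list(open, na_bound, total), each a numeric vector along temp.
.partition_i <- function(model, temp, na, caps) {
  J1 <- equilibrium_constant(model$J1, temp)
  J2 <- equilibrium_constant(model$J2, temp)
  Kna <- .binding_term(model$K1, na, model$coop)
  Kc  <- .binding_term(model$K2, caps, model$coop)
  cp <- model$caps
  open_sum <- na_sum <- total <- 0
  for (s in 0:2) {
    Js <- switch(s + 1, 1, J1, J1 * J2)
    for (open in c(FALSE, TRUE)) {
      base <- Js *
        (if (open) model$L * (if (s >= 1) model$D else 1) *
           (if (s == 2) model$E else 1) else 1)
      A <- Kna * (if (s >= 1) model$G else 1) * (if (s == 2) model$H else 1) *
        (if (open) model$F_na else 1)
      B <- Kc * (if (open) cp$c_L else 1) * (if (s >= 1) cp$c_J1 else 1) *
        (if (s == 2) cp$c_J2 else 1)
      cell_total <- base * (1 + A + B + A * B * cp$c_Na)
      cell_na    <- base * (A + A * B * cp$c_Na)
      total <- total + cell_total
      na_sum <- na_sum + cell_na
      if (open) open_sum <- open_sum + cell_total
    }
  }
  list(open = open_sum, na_bound = na_sum, total = total)
}

#' Equilibrium open probability of an allosteric gating model
#'
#' Closed-form evaluation of \eqn{P_o(T, [\mathrm{Na}], [\mathrm{caps}])} as
#' the ratio of open-state statistical weights to the full partition function.
#' Agrees with the brute-force [enumerate_states()] summation to machine
#' precision.
#'
#' @inheritParams enumerate_states
#' @param temp temperature(s) in kelvin; vectorized.
#' @return Numeric vector of open probabilities in \[0, 1\].
#' @export
open_probability <- function(model, temp, na = 0, caps = 0) {
  stopifnot(inherits(model, "allosteric_model"))
  .check_nonneg(na, "na"); .check_nonneg(caps, "caps")
  stopifnot(length(na) == 1L, length(caps) == 1L)
  z <- .partition_i(model, temp, na, caps)
  z$open / z$total
}

#' Equilibrium fraction of Na+-bound states
#'
#' The summed occupancy of all Na+-bound states at equilibrium, relative to
#' the full partition function. This is the quantity that scales the
#' Na+-dependent pre-factor of temperature-dependent inactivation
#' (see [inactivation_rate()]). Monotonically non-decreasing in `na`.
#'
#' @inheritParams open_probability
#' @return Numeric vector of bound fractions in \[0, 1\].
#' @export
fraction_na_bound <- function(model, temp, na = 0, caps = 0) {
  stopifnot(inherits(model, "allosteric_model"))
  .check_nonneg(na, "na"); .check_nonneg(caps, "caps")
  z <- .partition_i(model, temp, na, caps)
  z$na_bound / z$total
}
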