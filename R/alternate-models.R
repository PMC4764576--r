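#' Alternate gating model with Na+-dependent temperature-sensitive opening
#'
#' Constructs "model ii": an 8-state scheme in which, without external Na+,
#' a single temperature-dependent closed-closed transition (`J1`) precedes a
#' temperature-independent opening (`L`), followed by a temperature-dependent
#' open-open transition (`J2`). Na+ binding (association constant `K1`,
#' cooperative exponent `coop`) shifts the first transition by the factor `G`
#' and replaces the opening equilibrium with a temperature-dependent one
#' (`J3`) that is not available in the Na+-free branch.
#'
#' @param L temperature-independent opening equilibrium constant (Na+-free
#'   branch).
#' @param J1,J2,J3 [thermo_transition()] objects: first sensor step, open-open
#'   step, and the Na+-induced temperature-dependent opening.
#' @param G coupling factor of Na+ binding to the first transition.
#' @param K1 Na+ association constant, per molar.
#' @param coop cooperativity exponent on the Na+ binding term.
#' @return Object of class `gating_model_ii`.
#' @export
gating_model_ii <- function(L, J1, J2, J3, G = 1, K1 = 1, coop = 1.5) {
  stopifnot(inherits(J1, "thermo_transition"), inherits(J2, "thermo_transition"),
            inherits(J3, "thermo_transition"))
  for (nm in c("L", "G", "K1", "coop")) .check_positive(get(nm), nm)
  structure(list(L = L, J1 = J1, J2 = J2, J3 = J3, G = G, K1 = K1, coop = coop),
            class = "gating_model_ii")
}

# state weights of model ii at one condition; rows: 4 Na-free + 4 Na-bound
.states_ii <- function(model, temp, na) {
  J1 <- equilibrium_constant(model$J1, temp)
  J2 <- equilibrium_constant(model$J2, temp)
  J3 <- equilibrium_constant(model$J3, temp)
  Kna <- .binding_term(model$K1, na, model$coop)
  w_free  <- c(1, J1, J1 * model$L, J1 * model$L * J2)
  w_bound <- Kna * c(1, model$G * J1, model$G * J1 * J3, model$G * J1 * J3 * J2)
  data.frame(
    na_bound = rep(c(FALSE, TRUE), each = 4),
    pore = rep(c("closed", "closed", "open", "open"), 2),
    weight = c(w_free, w_bound))
}

#' Open probability of gating model ii
#'
#' @param model a [gating_model_ii()].
#' @param temp temperature(s), kelvin.
#' @param na external Na+ concentration, molar.
#' @return Open probabilities in \[0, 1\].
#' @export
open_probability_model_ii <- function(model, temp, na = 0) {
  stopifnot(inherits(model, "gating_model_ii"))
  .check_nonneg(na, "na")
  J1 <- equilibrium_constant(model$J1, temp)
  J2 <- equilibrium_constant(model$J2, temp)
  J3 <- equilibrium_constant(model$J3, temp)
  Kna <- .binding_term(model$K1, na, model$coop)
  open  <- J1 * model$L * (1 + J2) + Kna * model$G * J1 * J3 * (1 + J2)
  total <- 1 + J1 + J1 * model$L * (1 + J2) +
    Kna * (1 + model$G * J1 * (1 + J3 * (1 + J2)))
  open / total
}

#' Single-sensor allosteric gating model
#'
#' Constructs "model iii": the single-temperature-sensor reduction of the main
#' allosteric model. One temperature-dependent sensor step (`J1`) is coupled
#' to pore opening by the factor `D`; Na+ binding (association constant `K1`,
#' factors `F_na` on opening and `G` on the sensor) completes the 8-state
#' cube.
#'
#' @param L intrinsic opening equilibrium constant.
#' @param J1 [thermo_transition()] of the sensor step.
#' @param D coupling factor of the sensor to opening.
#' @param K1 Na+ association constant, per molar.
#' @param F_na,G coupling factors of Na+ binding to opening and to the sensor.
#' @param coop cooperativity exponent on the Na+ binding term.
#' @return Object of class `gating_model_iii`.
#' @export
gating_model_iii <- function(L, J1, D = 1, K1 = 1, F_na = 1, G = 1,
                             coop = 1.5) {
  stopifnot(inherits(J1, "thermo_transition"))
  for (nm in c("L", "D", "K1", "F_na", "G", "coop"))
    .check_positive(get(nm), nm)
  structure(list(L = L, J1 = J1, D = D, K1 = K1, F_na = F_na, G = G,
                 coop = coop),
            class = "gating_model_iii")
}

#' Open probability of gating model iii
#'
#' @param model a [gating_model_iii()].
#' @param temp temperature(s), kelvin.
#' @param na external Na+ concentration, molar.
#' @return Open probabilities in \[0, 1\].
#' @export
open_probability_model_iii <- function(model, temp, na = 0) {
  stopifnot(inherits(model, "gating_model_iii"))
  .check_nonneg(na, "na")
  J1 <- equilibrium_constant(model$J1, temp)
  Kna <- .binding_term(model$K1, na, model$coop)
  open <- total <- 0
  for (s in 0:1) {
    Js <- if (s == 1) J1 else 1
    for (op in c(FALSE, TRUE)) {
      base <- Js * (if (op) model$L * (if (s == 1) model$D else 1) else 1)
      A <- Kna * (if (s == 1) model$G else 1) * (if (op) model$F_na else 1)
      total <- total + base * (1 + A)
      if (op) open <- open + base * (1 + A)
    }
  }
  open / total
}
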