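#' Current-temperature relation
#'
#' Container for one cell/condition's macroscopic current as a function of
#' bath temperature (steady-state currents sampled during a temperature ramp
#' at a fixed test potential).
#'
#' @param temp temperatures; kelvin by default, Celsius with
#'   `unit = "C"`.
#' @param I currents (pA, or normalized).
#' @param voltage test potential, mV.
#' @param condition free-text condition label (e.g. `"130 Na"`).
#' @param unit `"K"` or `"C"`.
#' @return Object of class `it_relation`: data frame with columns `T_K`, `I`.
#' @export
it_relation <- function(temp, I, voltage = 90, condition = "", unit = c("K", "C")) {
  unit <- match.arg(unit)
  if (unit == "C") temp <- celsius_to_kelvin(temp)
  stopifnot(length(temp) == length(I))
  if (any(temp <= 250) || any(temp >= 350))
    stop("temperatures out of the physiological range (250, 350) K", call. = FALSE)
  structure(data.frame(T_K = temp, I = I),
            voltage = voltage, condition = condition,
            class = c("it_relation", "data.frame"))
}

#' Read/write current-temperature relations as CSV
#'
#' CSV dialect: columns `T_celsius`, `I_pA`, `voltage_mV` (constant).
#'
#' @param path CSV file path.
#' @param condition condition label attached on read.
#' @return An [it_relation()] (read) or `path` invisibly (write).
#' @export
read_it_relation <- function(path, condition = "") {
  d <- utils::read.csv(path)
  stopifnot(all(c("T_celsius", "I_pA") %in% names(d)))
  v <- if ("voltage_mV" %in% names(d)) d$voltage_mV[1] else 90
  it_relation(d$T_celsius, d$I_pA, voltage = v, condition = condition,
              unit = "C")
}

#' @rdname read_it_relation
#' @param rel an [it_relation()].
#' @export
write_it_relation <- function(rel, path) {
  stopifnot(inherits(rel, "it_relation"))
  utils::write.csv(
    data.frame(T_celsius = kelvin_to_celsius(rel$T_K), I_pA = rel$I,
               voltage_mV = attr(rel, "voltage")),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Open-probability-temperature relation
#'
#' @param temp temperatures, kelvin.
#' @param Po open probabilities (possibly unscaled, i.e. proportional to the
#'   true open probability).
#' @param sem optional per-point standard errors.
#' @param scale_ref scaling provenance: `NULL` while unscaled, otherwise a
#'   list recorded by [scale_pot()].
#' @return Object of class `pot_relation`: data frame with columns `T_K`,
#'   `Po` (and `sem` when given).
#' @export
pot_relation <- function(temp, Po, sem = NULL, scale_ref = NULL) {
  stopifnot(length(temp) == length(Po))
  d <- data.frame(T_K = temp, Po = Po)
  if (!is.null(sem)) d$sem <- sem
  structure(d, scale_ref = scale_ref, class = c("pot_relation", "data.frame"))
}

#' Arrhenius model of open-channel conduction
#'
#' Single-channel current as a function of temperature,
#' \eqn{i(T) = i_0 \exp(-\Delta H^{\ne}/RT)}: an activation-enthalpy barrier
#' for ion conduction through the open pore. The canonical enthalpy for this
#' channel is 9 kcal/mol.
#'
#' @param i0 pre-exponential amplitude, pA.
#' @param dH activation enthalpy for conduction, kcal/mol. Default 9.
#' @return Object of class `conduction_model`.
#' @export
#' @examples
#' cm <- conduction_model(i0 = 1, dH = 9)
#' open_channel_current(cm, c(295, 305))
conduction_model <- function(i0 = 1, dH = 9) {
  .check_positive(i0, "i0")
  structure(list(i0 = i0, dH = dH), class = "conduction_model")
}

#' @rdname conduction_model
#' @param cm a `conduction_model`.
#' @param temp temperature(s), kelvin.
#' @return `open_channel_current()`: single-channel current(s), pA.
#' @export
open_channel_current <- function(cm, temp) {
  stopifnot(inherits(cm, "conduction_model"))
  if (any(temp <= 0)) stop("temperature must be positive", call. = FALSE)
  cm$i0 * exp(-cm$dH / (.const$R_kcal * temp))
}

#' Fit the exponential (apparent-enthalpy) temperature dependence
#'
#' Fits \eqn{I(T) = \exp(-(\Delta H_{app} - T \Delta S_{app})/RT)} to the
#' steep portion of a current-temperature (or open-probability-temperature)
#' relation. The fit is performed as ordinary least squares on the log scale:
#' \eqn{\ln I} is affine in \eqn{1/T} with slope \eqn{-\Delta H_{app}/R} and
#' intercept \eqn{\Delta S_{app}/R}. On normalized data the
#' \eqn{\Delta H/\Delta S} pair is degenerate with an overall amplitude, so
#' \eqn{\Delta H_{app}} is the quantity to interpret.
#'
#' @param rel an [it_relation()] or [pot_relation()], or a data frame with a
#'   temperature column `T_K` and a value column (`I` or `Po`).
#' @param T_range optional length-2 kelvin interval restricting the fit.
#' @return Object of class `fit_result` with `estimate` containing `dHapp`
#'   (kcal/mol) and `dSapp` (kcal/(mol K)), plus residuals and the fitted lm.
#' @export
fit_exponential_enthalpy <- function(rel, T_range = NULL) {
  val_col <- if ("I" %in% names(rel)) "I" else "Po"
  temp <- rel$T_K; y <- rel[[val_col]]
  if (!is.null(T_range)) {
    keep <- temp >= min(T_range) & temp <= max(T_range)
    temp <- temp[keep]; y <- y[keep]
  }
  if (length(temp) < 4)
    stop("need at least 4 samples in the fitted temperature range", call. = FALSE)
  if (any(y <= 0))
    stop("non-positive currents in the fitted range: log-scale fit undefined",
         call. = FALSE)
  R <- .const$R_kcal
  fit <- stats::lm(log(y) ~ I(1 / temp))
  b <- stats::coef(fit)
  fit_result(
    estimate = c(dHapp = -unname(b[2]) * R, dSapp = unname(b[1]) * R),
    se = {
      # suppress the "essentially perfect fit" note on noiseless input
      s <- suppressWarnings(sqrt(diag(stats::vcov(fit))))
      c(dHapp = unname(s[2]) * R, dSapp = unname(s[1]) * R)
    },
    residuals = stats::residuals(fit),
    fitted = exp(stats::fitted(fit)),
    objective = "OLS of ln(I) on 1/T")
}

#' Divide out the conduction temperature dependence from an I-T relation
#'
#' Computes the unscaled open-probability-temperature relation as the
#' quotient between the measured currents and the Arrhenius single-channel
#' current, \eqn{P_o^{unscaled}(T) = I(T)/i(T)}. If the currents were
#' generated as \eqn{N i(T) P_o(T)}, the result is proportional to
#' \eqn{P_o(T)}; absolute scale is set later by [scale_pot()].
#'
#' @param rel an [it_relation()].
#' @param cm a [conduction_model()].
#' @return An unscaled [pot_relation()].
#' @export
it_to_pot <- function(rel, cm) {
  stopifnot(inherits(rel, "it_relation"), inherits(cm, "conduction_model"))
  i <- open_channel_current(cm, rel$T_K)
  if (any(i == 0)) stop("zero conduction current", call. = FALSE)
  pot_relation(rel$T_K, rel$I / i)
}

#' Average relations across cells with fixed-width temperature binning
#'
#' Pools several current- or open-probability-temperature relations, bins
#' them on a fixed-width temperature grid (replacing manual matching of
#' similar temperatures across cells), and returns per-bin means with
#' standard errors on both axes. Bins containing fewer than two points are
#' dropped.
#'
#' @param rels list of [it_relation()] or [pot_relation()] objects.
#' @param T_bin bin width, kelvin. Default 1.
#' @return Data frame with columns `T_K`, `T_sem`, `value`, `sem`, `n`;
#'   attribute `empty` is `TRUE` when no bin had two or more members.
#' @export
average_relations <- function(rels, T_bin = 1) {
  stopifnot(is.list(rels), length(rels) >= 2, T_bin > 0)
  val_col <- if ("I" %in% names(rels[[1]])) "I" else "Po"
  temp <- unlist(lapply(rels, `[[`, "T_K"))
  val <- unlist(lapply(rels, `[[`, val_col))
  bin <- floor(temp / T_bin)
  sem <- function(x) if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else NA_real_
  agg <- do.call(rbind, lapply(split(seq_along(temp), bin), function(ix) {
    data.frame(T_K = mean(temp[ix]), T_sem = sem(temp[ix]),
               value = mean(val[ix]), sem = sem(val[ix]), n = length(ix))
  }))
  agg <- agg[agg$n >= 2, , drop = FALSE]
  agg <- agg[order(agg$T_K), , drop = FALSE]
  rownames(agg) <- NULL
  if (nrow(agg) == 0) {
    warning("no temperature bin had two or more members; empty result")
    attr(agg, "empty") <- TRUE
  } else attr(agg, "empty") <- FALSE
  agg
}

#' Scale an open-probability-temperature relation to an absolute reference
#'
#' Places an unscaled relation on an absolute open-probability scale using
#' the relative macroscopic current magnitude at the reference temperature:
#' the scaled curve satisfies
#' \eqn{P_o(T_{ref}) = P_o^{ref} \times r}, where \eqn{r} is the ratio of the
#' condition's current to the reference condition's current at \eqn{T_{ref}}
#' (both at the same test potential) and \eqn{P_o^{ref}} is the absolute open
#' probability of the reference condition (canonically ~0.9 for saturating
#' capsaicin with 130 mM external Na+ at +90 mV and room temperature).
#' Chained scaling through an intermediate reference condition is supported:
#' pass the intermediate's `scale_ref` as `parent`; provenance is recorded.
#'
#' @param rel unscaled (or previously scaled) [pot_relation()].
#' @param current_ratio_at_ref ratio of this condition's current to the
#'   reference condition's current at `ref_T_K`.
#' @param reference_Po absolute open probability of the reference condition
#'   at `ref_T_K`, in (0, 1\].
#' @param ref_T_K reference temperature, kelvin. Default 295.15 (22 C).
#' @param condition,reference_condition labels recorded in the provenance.
#' @param parent optional `scale_ref` of the intermediate reference when
#'   chaining.
#' @param tol_K when no sample falls at `ref_T_K`, the nearest sample within
#'   `tol_K` kelvin is used (and flagged in the provenance). Default 1.
#' @return A scaled [pot_relation()] with full provenance in `scale_ref`.
#' @export
scale_pot <- function(rel, current_ratio_at_ref, reference_Po,
                      ref_T_K = 295.15, condition = "", reference_condition = "",
                      parent = NULL, tol_K = 1) {
  stopifnot(inherits(rel, "pot_relation"))
  if (!(reference_Po > 0 && reference_Po <= 1))
    stop("`reference_Po` must be in (0, 1]", call. = FALSE)
  .check_positive(current_ratio_at_ref, "current_ratio_at_ref")
  k <- which.min(abs(rel$T_K - ref_T_K))
  if (abs(rel$T_K[k] - ref_T_K) > tol_K)
    stop(sprintf("no sample within %g K of the reference temperature %g K",
                 tol_K, ref_T_K), call. = FALSE)
  target <- reference_Po * current_ratio_at_ref
  factor <- target / rel$Po[k]
  Po_new <- rel$Po * factor
  if (any(Po_new > 1 + 1e-9)) {
    bad <- rel$T_K[which.max(Po_new)]
    stop(sprintf(
      "scaling pushes Po above 1 (max %.4g at T = %.2f K); check the reference",
      max(Po_new), bad), call. = FALSE)
  }
  prov <- list(condition = condition,
               reference_condition = reference_condition,
               reference_Po = reference_Po,
               reference_T_K = ref_T_K,
               matched_T_K = rel$T_K[k],
               current_ratio = current_ratio_at_ref,
               factor = factor,
               parent = parent)
  pot_relation(rel$T_K, Po_new,
               sem = if ("sem" %in% names(rel)) rel$sem * factor,
               scale_ref = prov)
}

#' Approximate Q10 from an apparent enthalpy
#'
#' Fold-change of the fitted quantity per 10 degrees,
#' \eqn{Q_{10} \approx e^{\Delta H_{app}/20}} (enthalpy in kcal/mol).
#'
#' @param dHapp apparent enthalpy, kcal/mol.
#' @return Dimensionless Q10.
#' @export
#' @examples
#' q10_from_enthalpy(45)  # ~9.49
q10_from_enthalpy <- function(dHapp) exp(dHapp / 20)

#' Container for fit results
#'
#' Uniform return value of the package's fitting routines: parameter
#' estimates, standard errors, residuals and a description of the objective.
#'
#' @param estimate named numeric vector of parameter estimates.
#' @param se named numeric vector of standard errors (may contain `NA`).
#' @param residuals numeric residual vector.
#' @param fitted fitted values.
#' @param objective character description of the objective/oracle used.
#' @param extra optional list of method-specific extras.
#' @return Object of class `fit_result`.
#' @export
fit_result <- function(estimate, se = NULL, residuals = NULL, fitted = NULL,
                       objective = "", extra = list()) {
  structure(list(estimate = estimate, se = se, residuals = residuals,
                 fitted = fitted, objective = objective, extra = extra),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result> ", x$objective, "\n", sep = "")
  tab <- data.frame(estimate = x$estimate)
  if (!is.null(x$se)) tab$se <- x$se[names(x$estimate)]
  print(tab)
  invisible(x)
}
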