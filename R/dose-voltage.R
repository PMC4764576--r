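#' Hill dose-response parameters
#'
#' Parameter set of the Hill equation in the inhibition convention used for
#' external Na+: `Imax` is the response at zero ligand (maximal activation,
#' since Na+ is the inhibitor) and `Imin` the response at saturating ligand,
#' \deqn{I([X]) = I_{min} + \frac{I_{max} - I_{min}}
#'   {1 + ([X]/K_{1/2})^s}.}
#'
#' @param Imin,Imax normalized current bounds (saturating-ligand and
#'   zero-ligand responses).
#' @param K12 half-maximal concentration, molar.
#' @param s Hill coefficient.
#' @return Object of class `hill_params`.
#' @export
#' @examples
#' p <- hill_params(Imin = 0, Imax = 1, K12 = 7e-3, s = 1.2)
#' hill_eval(p, c(0, 7e-3, 130e-3))
hill_params <- function(Imin, Imax, K12, s) {
  .check_positive(K12, "K12"); .check_positive(s, "s")
  stopifnot(is.numeric(Imin), is.numeric(Imax))
  structure(list(Imin = Imin, Imax = Imax, K12 = K12, s = s),
            class = "hill_params")
}

#' Evaluate the Hill equation
#'
#' @param p a [hill_params()].
#' @param conc ligand concentration(s), molar (>= 0). `conc = 0` returns
#'   `Imax`; `conc -> Inf` returns `Imin`; `conc = K12` the midpoint.
#' @return Normalized responses.
#' @export
hill_eval <- function(p, conc) {
  stopifnot(inherits(p, "hill_params"))
  .check_nonneg(conc, "conc")
  p$Imin + (p$Imax - p$Imin) / (1 + (conc / p$K12)^p$s)
}

#' Fit the Hill equation to a dose-response relation
#'
#' Bounded nonlinear least squares (Levenberg-Marquardt) of the Hill
#' equation, with \eqn{K_{1/2}} fitted on the log scale to enforce
#' positivity. Bounds and fixed parameters are supported; by default all
#' four parameters (`Imin`, `Imax`, `K12`, `s`) are free.
#'
#' @param conc concentrations, molar; at least 4 distinct values.
#' @param response normalized responses.
#' @param fixed optional named list fixing a subset of `Imin`, `Imax`,
#'   `K12`, `s`.
#' @param start optional named list of starting values (sensible defaults
#'   otherwise).
#' @return A [fit_result()] whose `extra$params` is the fitted
#'   [hill_params()].
#' @export
#' @examples
#' p <- hill_params(0, 1, 7e-3, 1.2)
#' conc <- c(0, 1, 3, 10, 30, 65, 130) * 1e-3
#' fit <- hill_fit(conc, hill_eval(p, conc))
#' fit$estimate
hill_fit <- function(conc, response, fixed = list(), start = list()) {
  stopifnot(length(conc) == length(response))
  if (length(unique(conc)) < 4)
    stop("need at least 4 distinct concentrations", call. = FALSE)
  .check_nonneg(conc, "conc")
  pos <- conc[conc > 0]
  defaults <- list(Imin = min(response), Imax = max(response),
                   K12 = exp(mean(log(range(pos)))), s = 1)
  start <- utils::modifyList(defaults, start)
  free <- setdiff(c("Imin", "Imax", "K12", "s"), names(fixed))
  th0 <- unlist(start[free])
  if ("K12" %in% free) th0["K12"] <- log(th0["K12"])
  if ("s" %in% free) th0["s"] <- log(th0["s"])

  build <- function(th) {
    p <- as.list(th)
    if ("K12" %in% free) p$K12 <- exp(p$K12)
    if ("s" %in% free) p$s <- exp(p$s)
    p <- utils::modifyList(p, fixed)
    hill_params(p$Imin, p$Imax, p$K12, p$s)
  }
  resid_fn <- function(th) response - hill_eval(build(th), conc)
  nls_out <- minpack.lm::nls.lm(
    par = th0, fn = resid_fn,
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                         ptol = 1e-14))
  if (nls_out$info == 0 || nls_out$info == 9)
    stop("Hill fit did not converge: ", nls_out$message, call. = FALSE)
  p_hat <- build(nls_out$par)
  # delta-method SEs back on the natural scale
  se <- tryCatch({
    covm <- tryCatch(stats::vcov(nls_out), error = function(e) NULL)
    if (is.null(covm)) NULL else {
      s_raw <- sqrt(diag(covm))
      names(s_raw) <- names(nls_out$par)
      if ("K12" %in% free) s_raw["K12"] <- s_raw["K12"] * p_hat$K12
      if ("s" %in% free) s_raw["s"] <- s_raw["s"] * p_hat$s
      s_all <- stats::setNames(rep(NA_real_, 4), c("Imin", "Imax", "K12", "s"))
      s_all[names(s_raw)] <- s_raw
      s_all
    }
  }, error = function(e) NULL)
  fit_result(
    estimate = c(Imin = p_hat$Imin, Imax = p_hat$Imax,
                 K12 = p_hat$K12, s = p_hat$s),
    se = se,
    residuals = resid_fn(nls_out$par),
    fitted = hill_eval(p_hat, conc),
    objective = "Levenberg-Marquardt NLS, Hill equation (log-scale K12, s)",
    extra = list(params = p_hat, deviance = nls_out$deviance))
}

#' Voltage dependence of the half-inhibiting Na+ concentration
#'
#' Fits \eqn{K_{1/2}(V) = K_{1/2}(0) \exp(-z\delta V / k_B T)} by log-linear
#' regression of \eqn{\ln K_{1/2}} against voltage, returning the
#' zero-voltage affinity and the effective charge \eqn{z\delta}.
#'
#' @param V_mV voltages, mV (>= 3 values).
#' @param K12 half-maximal concentrations, molar (positive).
#' @param temp temperature, kelvin. Default 295.15.
#' @return A [fit_result()] with estimates `K12_0` (molar) and `z_delta`
#'   (elementary charges).
#' @export
fit_k12_voltage <- function(V_mV, K12, temp = 295.15) {
  stopifnot(length(V_mV) == length(K12))
  if (length(V_mV) < 3) stop("need at least 3 voltages", call. = FALSE)
  if (any(K12 <= 0)) stop("K12 values must be positive", call. = FALSE)
  fit <- stats::lm(log(K12) ~ V_mV)
  b <- stats::coef(fit)
  kBT_mV <- .const$kB_mV * temp  # mV
  se <- suppressWarnings(sqrt(diag(stats::vcov(fit))))
  fit_result(
    estimate = c(K12_0 = exp(unname(b[1])),
                 z_delta = -unname(b[2]) * kBT_mV),
    se = c(K12_0 = exp(unname(b[1])) * unname(se[1]),
           z_delta = unname(se[2]) * kBT_mV),
    residuals = stats::residuals(fit),
    fitted = exp(stats::fitted(fit)),
    objective = "OLS of ln(K12) on V")
}

#' Goldman-Hodgkin-Katz current model with Boltzmann gating
#'
#' Parameters of the theoretical current-voltage relation
#' \deqn{I(V) = N\left[P_{o,min} + \frac{P_{o,max} - P_{o,min}}
#'   {1 + e^{-zF(V - V_{1/2})/RT}}\right] \Phi(V)}
#' where the constant-field flux term
#' \deqn{\Phi(V) = P_{X1} F \left[z_{X1} [X1]_i\, g(u_1) -
#'   f z_{X2} [X2]_o\, g(-u_2)\right], \quad
#'   g(u) = \frac{u}{1 - e^{-u}}, \; u_k = z_{Xk} F V / RT,}
#' carries the permeability ratio `f` on the external-ion (inward) summand
#' only. The removable singularity at \eqn{V = 0} is handled by a
#' second-order series expansion of \eqn{g}.
#'
#' @param N channel count.
#' @param Po_min,Po_max open-probability bounds of the Boltzmann factor.
#' @param z gating charge, elementary charges.
#' @param V12 half-activation voltage, mV.
#' @param P_X1 permeability of the internal cation, m/s.
#' @param z_X1,z_X2 internal and external ion charges.
#' @param X1_in,X2_out internal and external concentrations, molar.
#' @param f permeability ratio \eqn{P_{X2}/P_{X1}} (>= 0).
#' @return Object of class `ghk_params`.
#' @export
ghk_params <- function(N = 1, Po_min = 0, Po_max = 1, z = 1, V12 = 0,
                       P_X1, z_X1 = 1, z_X2 = 1, X1_in, X2_out, f = 1) {
  stopifnot(Po_min >= 0, Po_max <= 1, Po_min <= Po_max, f >= 0)
  .check_positive(P_X1, "P_X1")
  .check_nonneg(X1_in, "X1_in"); .check_nonneg(X2_out, "X2_out")
  structure(list(N = N, Po_min = Po_min, Po_max = Po_max, z = z, V12 = V12,
                 P_X1 = P_X1, z_X1 = z_X1, z_X2 = z_X2,
                 X1_in = X1_in, X2_out = X2_out, f = f),
            class = "ghk_params")
}

# g(u) = u / (1 - exp(-u)), series-expanded near 0 (|u| < 1e-4)
.ghk_g <- function(u) {
  out <- numeric(length(u))
  small <- abs(u) < 1e-4
  out[small] <- 1 + u[small] / 2 + u[small]^2 / 12
  us <- u[!small]
  out[!small] <- us / (1 - exp(-us))
  out
}

#' Theoretical current-voltage relation
#'
#' Evaluates the [ghk_params()] model on a voltage grid. Currents are in pA
#' (permeability in m/s, concentrations molar).
#'
#' @param p a [ghk_params()].
#' @param V_mV voltage grid, mV.
#' @param temp temperature, kelvin. Default 295.15.
#' @return Numeric currents (pA), same length as `V_mV`.
#' @export
#' @examples
#' p <- ghk_params(N = 1, Po_min = 0.05, Po_max = 0.9, z = 0.31, V12 = 71,
#'                 P_X1 = 2.04721e-19, X1_in = 0.130, X2_out = 0.130, f = 1)
#' ghk_iv(p, seq(-120, 120, 30))
ghk_iv <- function(p, V_mV, temp = 295.15) {
  stopifnot(inherits(p, "ghk_params"))
  if (any(!is.finite(V_mV))) stop("voltage grid must be finite", call. = FALSE)
  .check_positive(temp, "temp")
  V <- V_mV * 1e-3                       # volts
  Fc <- .const$F_C; RT <- .const$R_J * temp
  u1 <- p$z_X1 * Fc * V / RT
  u2 <- p$z_X2 * Fc * V / RT
  C_in <- p$X1_in * 1e3                  # mol/m^3
  C_out <- p$X2_out * 1e3
  flux <- p$P_X1 * Fc *
    (p$z_X1 * C_in * .ghk_g(u1) - p$f * p$z_X2 * C_out * .ghk_g(-u2))
  po <- p$Po_min + (p$Po_max - p$Po_min) /
    (1 + exp(-p$z * Fc * (V - p$V12 * 1e-3) / RT))
  p$N * po * flux * 1e12                 # amperes -> pA
}

#' Dose-response table
#'
#' @param conc ligand concentrations, molar.
#' @param response normalized currents.
#' @param sem optional standard errors.
#' @return Object of class `dose_response` (a data frame).
#' @export
dose_response <- function(conc, response, sem = NULL) {
  .check_nonneg(conc, "conc")
  stopifnot(length(conc) == length(response), all(is.finite(response)))
  d <- data.frame(conc_M = conc, response = response)
  if (!is.null(sem)) d$sem <- sem
  structure(d, class = c("dose_response", "data.frame"))
}

#' Read/write dose-response tables as CSV
#'
#' CSV dialect: columns `conc_M`, `response` and optional `sem`.
#'
#' @param path CSV file path.
#' @return A [dose_response()] (read) or `path` invisibly (write).
#' @export
read_dose_response <- function(path) {
  d <- utils::read.csv(path)
  stopifnot(all(c("conc_M", "response") %in% names(d)))
  dose_response(d$conc_M, d$response, sem = d$sem)
}

#' @rdname read_dose_response
#' @param dr a [dose_response()].
#' @export
write_dose_response <- function(dr, path) {
  utils::write.csv(as.data.frame(dr), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
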