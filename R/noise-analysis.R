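#' Ensemble of current sweeps for noise analysis
#'
#' Holds the repeated equal-length current traces recorded at a fixed test
#' potential (one column per sweep) that non-stationary noise analysis
#' consumes, together with the sampling interval and the steady-state window.
#'
#' @param sweeps numeric matrix, rows = time points, columns = sweeps (in
#'   recording order; successive-difference analysis depends on the order).
#' @param sample_interval sampling interval, seconds.
#' @param steady_state_window integer vector of row indices regarded as
#'   steady state. Default: all rows.
#' @return Object of class `sweep_ensemble`.
#' @export
sweep_ensemble <- function(sweeps, sample_interval = 1e-4,
                           steady_state_window = seq_len(nrow(sweeps))) {
  sweeps <- as.matrix(sweeps)
  if (ncol(sweeps) < 3) stop("need at least 3 sweeps", call. = FALSE)
  stopifnot(all(steady_state_window >= 1),
            all(steady_state_window <= nrow(sweeps)))
  structure(list(sweeps = sweeps, sample_interval = sample_interval,
                 steady_state_window = steady_state_window),
            class = "sweep_ensemble")
}

#' Successive-difference current variance
#'
#' Estimates the per-time-point current variance from an ordered sweep
#' ensemble using scaled differences of successive records,
#' \deqn{y_j = \tfrac{1}{2}(x_j - x_{j+1}), \qquad
#'   \sigma_I^2 = \frac{2}{N-2} \sum_{j=1}^{N-1} (y_j - \bar y)^2,}
#' where \eqn{N} is the number of sweeps. Because common slow drift (rundown)
#' cancels in successive differences to first order, this estimator is far
#' more robust to rundown than the naive ensemble variance
#' (see [ensemble_variance()]).
#'
#' @param ens a [sweep_ensemble()].
#' @return List with numeric vectors `sigma2` and `Imean` (per time point).
#' @export
successive_difference_variance <- function(ens) {
  stopifnot(inherits(ens, "sweep_ensemble"))
  x <- ens$sweeps
  n <- ncol(x)
  if (n < 3) stop("need at least 3 sweeps", call. = FALSE)
  y <- (x[, 1:(n - 1), drop = FALSE] - x[, 2:n, drop = FALSE]) / 2
  ybar <- rowMeans(y)
  sigma2 <- 2 / (n - 2) * rowSums((y - ybar)^2)
  list(sigma2 = sigma2, Imean = rowMeans(x))
}

#' Naive ensemble variance (for comparison)
#'
#' Plain per-time-point variance across sweeps. Unlike
#' [successive_difference_variance()], it is inflated by any slow common
#' drift of the sweep amplitudes; it is provided as the comparison baseline
#' for the drift-robustness property of the successive-difference estimator.
#'
#' @param ens a [sweep_ensemble()].
#' @return List with `sigma2` and `Imean`.
#' @export
ensemble_variance <- function(ens) {
  stopifnot(inherits(ens, "sweep_ensemble"))
  x <- ens$sweeps
  list(sigma2 = apply(x, 1, stats::var), Imean = rowMeans(x))
}

#' Correct noise statistics for leak and baseline variance
#'
#' Subtracts baseline (leak) mean current and variance - measured in a
#' declared baseline segment (canonically the holding potential in the
#' channel-silent condition) - from the test-segment statistics, and trims a
#' fraction of samples at both window edges to discard residual capacitive
#' transients.
#'
#' @param stats list with `sigma2` and `Imean` (from
#'   [successive_difference_variance()]).
#' @param baseline_sigma2,baseline_Imean scalar baseline statistics.
#' @param trim fraction of points dropped at each edge. Default 0.05.
#' @return List with corrected `sigma2`, `Imean` and logical
#'   `negative_variance_flag` set when more than 10% of corrected variances
#'   are negative.
#' @export
correct_leak_baseline <- function(stats, baseline_sigma2 = 0,
                                  baseline_Imean = 0, trim = 0.05) {
  n <- length(stats$sigma2)
  drop_n <- floor(n * trim)
  keep <- if (drop_n > 0) seq.int(drop_n + 1, n - drop_n) else seq_len(n)
  sigma2 <- stats$sigma2[keep] - baseline_sigma2
  Imean <- stats$Imean[keep] - baseline_Imean
  flag <- mean(sigma2 < 0) > 0.10
  if (flag)
    warning("more than 10% of corrected variances are negative; ",
            "baseline estimate may be too large")
  list(sigma2 = sigma2, Imean = Imean, negative_variance_flag = flag)
}

#' Fit the variance-mean parabola
#'
#' Least-squares fit of the binomial variance-mean relation
#' \deqn{\sigma_I^2 = I_{mean} i - I_{mean}^2/N}
#' to pooled \eqn{(\sigma^2, I)} points, yielding the single-channel current
#' \eqn{i} and channel count \eqn{N}. The relation is linear in \eqn{(i, 1/N)},
#' so the fit is exact (unweighted) linear least squares. Points from several
#' conditions (e.g. a low- and a high-open-probability segment) may be pooled
#' under the assumption of shared \eqn{i} and \eqn{N}; supplying `i_fixed`
#' constrains the unitary current from an external estimate and fits only
#' \eqn{N}.
#'
#' @param sigma2,Imean numeric vectors of variance and mean current (pA^2,
#'   pA); at least 10 pairs spanning a mean-current range of at least 1.2x.
#' @param i_fixed optional fixed single-channel current, pA.
#' @return Object of class `noise_fit`: list with `i_hat`, `N_hat`,
#'   `constrained`, and residuals.
#' @export
fit_variance_mean <- function(sigma2, Imean, i_fixed = NULL) {
  stopifnot(length(sigma2) == length(Imean))
  ok <- is.finite(sigma2) & is.finite(Imean)
  sigma2 <- sigma2[ok]; Imean <- Imean[ok]
  if (length(sigma2) < 10)
    stop("need at least 10 (variance, mean) pairs", call. = FALSE)
  Ipos <- Imean[Imean > 0]
  if (length(Ipos) < 2 || max(Ipos) / min(Ipos) < 1.2)
    stop("mean-current range too narrow (max/min < 1.2): i and N are not ",
         "jointly identifiable; pool data from a second condition",
         call. = FALSE)
  if (is.null(i_fixed)) {
    fit <- stats::lm(sigma2 ~ 0 + Imean + I(Imean^2))
    b <- stats::coef(fit)
    i_hat <- unname(b[1]); N_hat <- -1 / unname(b[2])
    constrained <- FALSE
  } else {
    .check_positive(i_fixed, "i_fixed")
    fit <- stats::lm(I(i_fixed * Imean - sigma2) ~ 0 + I(Imean^2))
    i_hat <- i_fixed; N_hat <- 1 / unname(stats::coef(fit)[1])
    constrained <- TRUE
  }
  if (!is.finite(i_hat) || !is.finite(N_hat) || i_hat <= 0 || N_hat <= 0)
    stop("variance-mean fit did not yield positive i and N; data may not ",
         "span enough of the parabola", call. = FALSE)
  structure(list(i_hat = i_hat, N_hat = N_hat, constrained = constrained,
                 residuals = stats::residuals(fit)),
            class = "noise_fit")
}

#' @export
print.noise_fit <- function(x, ...) {
  cat(sprintf("<noise_fit> i = %.4g pA%s, N = %.4g\n", x$i_hat,
              if (x$constrained) " (fixed)" else "", x$N_hat))
  invisible(x)
}

#' Absolute open probability from noise-analysis estimates
#'
#' \eqn{P_o = I_{mean,ss} / (i N)} from a fitted [fit_variance_mean()] result
#' and the steady-state mean current of the condition of interest. Estimates
#' slightly above 1 are reported clipped to 1 with a warning.
#'
#' @param fit a `noise_fit`.
#' @param Imean_ss steady-state mean current, pA (same sign convention as the
#'   data used for the fit).
#' @return Open probability in \[0, 1\].
#' @export
open_prob_from_noise <- function(fit, Imean_ss) {
  stopifnot(inherits(fit, "noise_fit"), Imean_ss >= 0)
  denom <- fit$i_hat * fit$N_hat
  if (denom == 0) stop("i * N is zero", call. = FALSE)
  po <- Imean_ss / denom
  if (po > 1) {
    warning(sprintf("estimated Po = %.3f > 1; reporting 1 (estimator noise)", po))
    po <- 1
  }
  po
}

#' Read a sweep ensemble from CSV
#'
#' CSV dialect: one column `time_s` plus one column per sweep (any names),
#' in recording order.
#'
#' @param path CSV file path.
#' @param steady_state_window optional row-index window.
#' @return A [sweep_ensemble()].
#' @export
read_sweep_ensemble <- function(path, steady_state_window = NULL) {
  d <- utils::read.csv(path)
  stopifnot("time_s" %in% names(d))
  tcol <- d$time_s
  m <- as.matrix(d[setdiff(names(d), "time_s")])
  dt <- if (length(tcol) > 1) stats::median(diff(tcol)) else 1e-4
  sweep_ensemble(m, sample_interval = dt,
                 steady_state_window = steady_state_window %||% seq_len(nrow(m)))
}
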