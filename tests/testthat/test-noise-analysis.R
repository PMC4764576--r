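# Hybrid non-stationary/stationary noise analysis.

test_that("successive-difference variance matches hand evaluation", {
  # identical sweeps: zero variance
  x <- matrix(5, nrow = 10, ncol = 6)
  ens <- sweep_ensemble(x)
  sd0 <- successive_difference_variance(ens)
  expect_true(all(sd0$sigma2 == 0))
  expect_true(all(sd0$Imean == 5))
  # alternating constant sweeps a, b: y_j = +/-(a-b)/2, hand formula
  a <- 3; b <- 7; n <- 6
  x2 <- matrix(rep(c(a, b), length.out = n * 4), nrow = 4, ncol = n,
               byrow = TRUE)
  s2 <- successive_difference_variance(sweep_ensemble(x2))$sigma2
  y <- rep(c((a - b) / 2, (b - a) / 2), length.out = n - 1)
  expect_equal(s2, rep(2 / (n - 2) * sum((y - mean(y))^2), 4))
  expect_error(sweep_ensemble(matrix(0, 4, 2)), "3 sweeps")
})

test_that("successive differences cancel common drift, naive variance does not", {
  cfg <- sim_config(seed = 31, n_channels = 100, i_room = 1)
  ens <- gen_noise_ensemble(cfg, Po = 0.4, n_sweeps = 60, n_samples = 300,
                            rundown_frac = 0.2)
  sdv <- successive_difference_variance(ens)
  nav <- ensemble_variance(ens)
  # theoretical stationary variance (mid-rundown amplitude)
  true_var <- 100 * 0.4 * 0.6 * 0.9^2
  bias_sd <- abs(mean(sdv$sigma2) - true_var) / true_var
  bias_naive <- abs(mean(nav$sigma2) - true_var) / true_var
  expect_lt(bias_sd, 0.15)
  expect_gt(bias_naive, 5 * bias_sd)
})

test_that("leak/baseline correction subtracts and trims", {
  stats <- list(sigma2 = rep(4, 100), Imean = rep(10, 100))
  # zero baseline: identity apart from edge trimming
  out0 <- correct_leak_baseline(stats, 0, 0, trim = 0.05)
  expect_equal(length(out0$sigma2), 90)
  expect_true(all(out0$sigma2 == 4))
  # baseline equal to signal: zeros
  out1 <- correct_leak_baseline(stats, 4, 10)
  expect_true(all(out1$sigma2 == 0) && all(out1$Imean == 0))
  # over-subtraction flags negative variances
  expect_warning(out2 <- correct_leak_baseline(stats, 5, 0), "negative")
  expect_true(out2$negative_variance_flag)
})

test_that("leak correction recovers leak-free statistics on paired simulations", {
  cfg <- sim_config(seed = 77, n_channels = 200, i_room = 1.5)
  leak_mean <- 30; leak_sd <- 2
  ens_clean <- gen_noise_ensemble(cfg, Po = 0.5, n_sweeps = 50,
                                  n_samples = 400)
  ens_leaky <- gen_noise_ensemble(cfg, Po = 0.5, n_sweeps = 50,
                                  n_samples = 400, baseline_sd = leak_sd)
  ens_leaky$sweeps <- ens_leaky$sweeps + leak_mean
  s_clean <- successive_difference_variance(ens_clean)
  s_leaky <- successive_difference_variance(ens_leaky)
  corr <- correct_leak_baseline(s_leaky, baseline_sigma2 = leak_sd^2,
                                baseline_Imean = leak_mean, trim = 0)
  expect_equal(mean(corr$Imean), mean(s_clean$Imean), tolerance = 0.02)
  expect_equal(mean(corr$sigma2), mean(s_clean$sigma2), tolerance = 0.1)
})

test_that("variance-mean parabola inverts exactly on noiseless points", {
  i <- 2; N <- 400
  I <- seq(40, 700, length.out = 30)
  s2 <- I * i - I^2 / N
  fit <- fit_variance_mean(s2, I)
  expect_equal(fit$i_hat, 2, tolerance = 1e-9)
  expect_equal(fit$N_hat, 400, tolerance = 1e-9)
  # constrained mode: i fixed, only N fitted
  fitc <- fit_variance_mean(s2, I, i_fixed = 2)
  expect_true(fitc$constrained)
  expect_equal(fitc$N_hat, 400, tolerance = 1e-9)
  # non-identifiable narrow range
  In <- seq(100, 110, length.out = 12)
  expect_error(fit_variance_mean(In * i - In^2 / N, In), "narrow")
})

test_that("binomial moments lie exactly on the parabola", {
  # (I, sigma2) = (N i P, N i^2 P(1-P)) satisfies sigma2 = I i - I^2/N
  N <- 100; i <- 1
  P <- seq(0.05, 0.95, 0.05)
  I <- N * i * P
  s2 <- N * i^2 * P * (1 - P)
  expect_equal(s2, I * i - I^2 / N, tolerance = 1e-12)
  fit <- fit_variance_mean(s2, I)
  expect_equal(fit$i_hat, 1, tolerance = 1e-9)
  expect_equal(fit$N_hat, 100, tolerance = 1e-9)
})

test_that("two pooled conditions identify shared i and N", {
  cfg1 <- sim_config(seed = 41, n_channels = 400, i_room = 2)
  cfg2 <- sim_config(seed = 42, n_channels = 400, i_room = 2)
  lo <- gen_noise_ensemble(cfg1, Po = 0.2, n_sweeps = 50, n_samples = 300)
  hi <- gen_noise_ensemble(cfg2, Po = 0.9, n_sweeps = 50, n_samples = 300)
  s_lo <- successive_difference_variance(lo)
  s_hi <- successive_difference_variance(hi)
  fit <- fit_variance_mean(c(s_lo$sigma2, s_hi$sigma2),
                           c(s_lo$Imean, s_hi$Imean))
  expect_equal(fit$i_hat, 2, tolerance = 0.2)
  expect_equal(fit$N_hat, 400, tolerance = 0.15 * 400)
  po <- open_prob_from_noise(fit, mean(s_hi$Imean))
  expect_equal(po, 0.9, tolerance = 0.03)
})

test_that("open probability from noise estimates respects its limits", {
  fit <- structure(list(i_hat = 2, N_hat = 400, constrained = FALSE),
                   class = "noise_fit")
  expect_equal(open_prob_from_noise(fit, 800), 1)     # Imean = i N
  expect_equal(open_prob_from_noise(fit, 0), 0)
  expect_warning(po <- open_prob_from_noise(fit, 850), "> 1")
  expect_equal(po, 1)
})

test_that("estimator bias shrinks with sweep count", {
  est_po <- function(n_sweeps, seed) {
    cfg_lo <- sim_config(seed = seed, n_channels = 150, i_room = 1)
    cfg_hi <- sim_config(seed = seed + 1, n_channels = 150, i_room = 1)
    lo <- gen_noise_ensemble(cfg_lo, Po = 0.25, n_sweeps = n_sweeps,
                             n_samples = 200)
    hi <- gen_noise_ensemble(cfg_hi, Po = 0.8, n_sweeps = n_sweeps,
                             n_samples = 200)
    s_lo <- successive_difference_variance(lo)
    s_hi <- successive_difference_variance(hi)
    fit <- fit_variance_mean(c(s_lo$sigma2, s_hi$sigma2),
                             c(s_lo$Imean, s_hi$Imean))
    open_prob_from_noise(fit, mean(s_hi$Imean))
  }
  bias <- sapply(c(10, 50, 500), function(ns) {
    abs(mean(sapply(1:6, function(k) est_po(ns, 1000 * ns + 2 * k))) - 0.8)
  })
  expect_lt(bias[3], 0.02)
  expect_lt(bias[3], bias[1] + 0.01)  # monotone trend up to Monte-Carlo noise
})

test_that("rundown biases the successive-difference estimate far less than naive variance", {
  est_po_both <- function(rundown, seed) {
    cfg_lo <- sim_config(seed = seed, n_channels = 150, i_room = 1)
    cfg_hi <- sim_config(seed = seed + 1, n_channels = 150, i_room = 1)
    lo <- gen_noise_ensemble(cfg_lo, Po = 0.25, n_sweeps = 50,
                             n_samples = 300, rundown_frac = rundown)
    hi <- gen_noise_ensemble(cfg_hi, Po = 0.8, n_sweeps = 50,
                             n_samples = 300, rundown_frac = rundown)
    # steady-state mean and the fitted parabola come from the same ensemble
    # statistics, so the common mid-rundown amplitude factor cancels in
    # Imean/(i N); what remains is each variance estimator's corruption
    one <- function(fun) {
      s_lo <- fun(lo); s_hi <- fun(hi)
      fit <- fit_variance_mean(c(s_lo$sigma2, s_hi$sigma2),
                               c(s_lo$Imean, s_hi$Imean))
      suppressWarnings(open_prob_from_noise(fit, mean(s_hi$Imean)))
    }
    c(sd = one(successive_difference_variance), naive = one(ensemble_variance))
  }
  seeds <- 1:8
  clean <- rowMeans(sapply(seeds, function(k) est_po_both(0, 300 + 10 * k)))
  drift <- rowMeans(sapply(seeds, function(k) est_po_both(0.2, 600 + 10 * k)))
  bias_sd_clean <- abs(clean["sd"] - 0.8)
  bias_sd_drift <- abs(drift["sd"] - 0.8)
  bias_naive_drift <- abs(drift["naive"] - 0.8)
  expect_lt(bias_sd_drift, 3 * bias_sd_clean + 0.01)
  expect_gt(bias_naive_drift, 10 * max(bias_sd_clean, 0.005))
})

test_that("filtering the sweeps lowers the apparent single-channel current", {
  cfg_lo <- sim_config(seed = 61, n_channels = 200, i_room = 2)
  cfg_hi <- sim_config(seed = 62, n_channels = 200, i_room = 2)
  make_fit <- function(filtered) {
    prep <- function(ens) {
      if (filtered) {
        f <- rep(1 / 5, 5)  # 5-point boxcar, emulating low-pass filtering
        sm <- apply(ens$sweeps, 2, function(col)
          as.numeric(stats::filter(col, f, sides = 2)))
        keep <- !apply(is.na(sm), 1, any)
        ens$sweeps <- sm[keep, , drop = FALSE]
      }
      successive_difference_variance(ens)
    }
    lo <- prep(gen_noise_ensemble(cfg_lo, Po = 0.25, n_sweeps = 50,
                                  n_samples = 300))
    hi <- prep(gen_noise_ensemble(cfg_hi, Po = 0.8, n_sweeps = 50,
                                  n_samples = 300))
    fit_variance_mean(c(lo$sigma2, hi$sigma2), c(lo$Imean, hi$Imean))
  }
  i_raw <- make_fit(FALSE)$i_hat
  i_filt <- make_fit(TRUE)$i_hat
  expect_lt(i_filt, i_raw)  # direction only: filtering underestimates i
})
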