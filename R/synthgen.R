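#' Configuration for the synthetic-data generator
#'
#' Bundles everything the generator needs to emulate the recording protocols
#' the analysis pipeline assumes: a gating model, an Arrhenius conduction
#' model, channel count, room-temperature single-channel current, leak,
#' instrument noise and the temperature-ramp protocol. Identical
#' configurations (including `seed`) produce identical output.
#'
#' @param seed integer RNG seed (surfaced in generator output metadata).
#' @param model an [allosteric_model()].
#' @param conduction a [conduction_model()]; its `i0` is rescaled so that the
#'   single-channel current equals `i_room` pA at `T_room`.
#' @param n_channels channel count (>= 1).
#' @param i_room single-channel current at `T_room`, pA.
#' @param T_room room (reference) temperature, kelvin. Default 295.15.
#' @param leak constant leak current, pA.
#' @param noise_sd Gaussian instrument noise, pA.
#' @param ramp list with `T_start`, `T_end` (kelvin), `n` points and `shape`
#'   (`"sigmoid"` uses the ramp time-transform of
#'   [ramp_temperature_from_time()]; `"linear"` a uniform grid).
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, model = model_preset_illustrative(),
                       conduction = conduction_model(dH = 9),
                       n_channels = 1000, i_room = 1, T_room = 295.15,
                       leak = 0, noise_sd = 0,
                       ramp = list(T_start = 281, T_end = 318, n = 150,
                                   shape = "sigmoid")) {
  stopifnot(inherits(model, "allosteric_model"),
            inherits(conduction, "conduction_model"),
            n_channels >= 1)
  ramp_def <- list(T_start = 281, T_end = 318, n = 150, shape = "sigmoid")
  ramp <- utils::modifyList(ramp_def, ramp)
  stopifnot(ramp$shape %in% c("sigmoid", "linear"),
            ramp$T_start < ramp$T_end, ramp$n >= 2)
  # pin the conduction pre-factor so that i(T_room) = i_room
  conduction$i0 <- i_room / exp(-conduction$dH / (.const$R_kcal * T_room))
  structure(list(seed = as.integer(seed), model = model,
                 conduction = conduction, n_channels = n_channels,
                 i_room = i_room, T_room = T_room, leak = leak,
                 noise_sd = noise_sd, ramp = ramp),
            class = "sim_config")
}

# temperature grid of a configured ramp
.ramp_grid <- function(cfg) {
  r <- cfg$ramp
  if (r$shape == "linear") return(seq(r$T_start, r$T_end, length.out = r$n))
  # sample uniformly in ramp time and map through the sigmoid transform
  p <- inactivation_params()
  t <- seq(ramp_time_from_temperature(p, r$T_start),
           ramp_time_from_temperature(p, r$T_end), length.out = r$n)
  ramp_temperature_from_time(p, t)
}

#' Simulate a macroscopic current-temperature ramp
#'
#' Generates one cell's I-T relation,
#' \eqn{I(T_k) = N\, i(T_k)\, P_o(T_k)\, f_k + I_{leak} + \epsilon_k},
#' with \eqn{i(T)} from the Arrhenius conduction model, \eqn{P_o} from the
#' gating model at the requested Na+/capsaicin concentrations, an optional
#' inactivation survival factor \eqn{f_k}, and Gaussian instrument noise.
#'
#' @param cfg a [sim_config()].
#' @param na external Na+ concentration, molar.
#' @param caps capsaicin concentration, molar.
#' @param inactivation optional [inactivation_params()]; when supplied the
#'   pointwise survival overlay of [apply_inactivation()] is included.
#' @param amplitude_factor multiplicative cell-to-cell amplitude factor
#'   (expression-level scatter); applied to the noiseless current.
#' @return An [it_relation()]; the seed used is recorded in attribute
#'   `seed`.
#' @export
gen_it_ramp <- function(cfg, na = 0, caps = 0, inactivation = NULL,
                        amplitude_factor = 1) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  temp <- .ramp_grid(cfg)
  po <- open_probability(cfg$model, temp, na = na, caps = caps)
  if (!is.null(inactivation)) {
    eq <- pot_relation(temp, po)
    po <- apply_inactivation(eq, inactivation, cfg$model, na = na,
                             caps = caps)$Po
  }
  I <- cfg$n_channels * open_channel_current(cfg$conduction, temp) * po *
    amplitude_factor + cfg$leak +
    stats::rnorm(length(temp), sd = cfg$noise_sd)
  out <- it_relation(temp, I, condition = sprintf("na=%g M, caps=%g M", na, caps))
  attr(out, "seed") <- cfg$seed
  out
}

#' Simulate a sweep ensemble for noise analysis
#'
#' Simulates `n_sweeps` repeated current records from `cfg$n_channels`
#' independent two-state channels with stationary open probability `Po` and
#' single-channel current `i_chan`. With `correlation_time = 0` the open
#' counts are independent binomial draws per sample; otherwise channels
#' follow a stationary two-state Markov chain whose autocorrelation decays
#' with the given time constant. Optional per-sweep multiplicative rundown
#' and Gaussian baseline noise reproduce the main pathologies of real
#' ensembles.
#'
#' @param cfg a [sim_config()] (supplies `seed` and `n_channels`).
#' @param Po stationary open probability in \[0, 1\].
#' @param n_sweeps number of sweeps. Default 50.
#' @param n_samples samples per sweep. Default 200.
#' @param i_chan single-channel current, pA. Default `cfg$i_room`.
#' @param sample_interval seconds per sample. Default 1e-3.
#' @param correlation_time gating autocorrelation time, seconds (0 =
#'   independent samples).
#' @param rundown_frac total fractional linear amplitude rundown across the
#'   ensemble (e.g. 0.2 = the last sweep is 20% smaller). Default 0.
#' @param baseline_sd Gaussian baseline noise, pA. Default 0.
#' @return A [sweep_ensemble()]; attribute `seed` records the seed.
#' @export
gen_noise_ensemble <- function(cfg, Po, n_sweeps = 50, n_samples = 200,
                               i_chan = cfg$i_room, sample_interval = 1e-3,
                               correlation_time = 0, rundown_frac = 0,
                               baseline_sd = 0) {
  stopifnot(inherits(cfg, "sim_config"), Po >= 0, Po <= 1)
  set.seed(cfg$seed)
  N <- cfg$n_channels
  x <- matrix(0, nrow = n_samples, ncol = n_sweeps)
  for (s in seq_len(n_sweeps)) {
    if (correlation_time <= 0) {
      n_open <- stats::rbinom(n_samples, N, Po)
    } else {
      flip <- 1 - exp(-sample_interval / correlation_time)
      a <- Po * flip          # closed -> open
      b <- (1 - Po) * flip    # open -> closed
      n_open <- numeric(n_samples)
      n_open[1] <- stats::rbinom(1, N, Po)
      for (k in 2:n_samples) {
        stay <- stats::rbinom(1, n_open[k - 1], 1 - b)
        gain <- stats::rbinom(1, N - n_open[k - 1], a)
        n_open[k] <- stay + gain
      }
    }
    x[, s] <- i_chan * n_open
  }
  if (rundown_frac != 0 && n_sweeps > 1) {
    fac <- 1 - rundown_frac * (seq_len(n_sweeps) - 1) / (n_sweeps - 1)
    x <- sweep(x, 2, fac, `*`)
  }
  if (baseline_sd > 0)
    x <- x + matrix(stats::rnorm(length(x), sd = baseline_sd), nrow = n_samples)
  ens <- sweep_ensemble(x, sample_interval = sample_interval)
  attr(ens, "seed") <- cfg$seed
  ens
}

#' Simulate a dose-response table
#'
#' Hill-curve evaluation plus Gaussian noise on the response axis.
#'
#' @param cfg a [sim_config()] (supplies the seed).
#' @param hill a [hill_params()].
#' @param conc concentration grid, molar.
#' @param noise_sd Gaussian response noise. Default 0.
#' @return A [dose_response()]; attribute `seed` records the seed.
#' @export
gen_dose_response <- function(cfg, hill, conc, noise_sd = 0) {
  stopifnot(inherits(cfg, "sim_config"), inherits(hill, "hill_params"))
  set.seed(cfg$seed)
  r <- hill_eval(hill, conc) + stats::rnorm(length(conc), sd = noise_sd)
  dr <- dose_response(conc, r)
  attr(dr, "seed") <- cfg$seed
  dr
}

#' Simulate single-channel current amplitudes across temperatures
#'
#' Arrhenius single-channel currents with multiplicative Gaussian scatter,
#' emulating unitary-amplitude estimates from all-points histograms at
#' several bath temperatures.
#'
#' @param cfg a [sim_config()] (supplies seed and conduction model).
#' @param T_grid temperatures, kelvin, within (250, 350).
#' @param scatter_frac relative Gaussian scatter (e.g. 0.1 = 10%). Default 0.
#' @return `data.frame` with columns `T_K` and `i_pA`; attribute `seed`.
#' @export
gen_single_channel_amplitudes <- function(cfg, T_grid, scatter_frac = 0) {
  stopifnot(inherits(cfg, "sim_config"),
            all(T_grid > 250), all(T_grid < 350))
  set.seed(cfg$seed)
  i <- open_channel_current(cfg$conduction, T_grid)
  i <- i * (1 + stats::rnorm(length(T_grid), sd = scatter_frac))
  out <- data.frame(T_K = T_grid, i_pA = i)
  attr(out, "seed") <- cfg$seed
  out
}
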