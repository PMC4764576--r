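# End-to-end workflows chaining simulation, conduction correction, averaging
# and absolute scaling, with provenance (config hash + seed) on every output.

# FNV-1a 32-bit hash of a string; used to stamp outputs with a config hash
# without pulling in a hashing dependency.
.fnv1a <- function(txt) {
  bytes <- utf8ToInt(txt)
  h <- 2166136261
  for (b in bytes) {
    # xor on the low byte only (b < 256); h is kept as a double mod 2^32
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b))
    # 32-bit modular multiply by the FNV prime, split to stay within 2^53
    h_lo <- h %% 65536
    h_hi <- (h - h_lo) / 65536
    h <- (h_lo * 16777619 + ((h_hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  lo <- h %% 65536
  sprintf("%04x%04x", as.integer((h - lo) / 65536), as.integer(lo))
}

.config_hash <- function(cfg_list) {
  .fnv1a(jsonlite::toJSON(cfg_list, auto_unbox = TRUE, digits = NA,
                          force = TRUE))
}

#' Run the open-probability-temperature pipeline on synthetic cells
#'
#' End-to-end desk-scale workflow reproducing the analysis chain applied to
#' ramp recordings: for each requested condition, simulate `n_cells`
#' current-temperature ramps, divide out the Arrhenius conduction
#' temperature-dependence, average across cells on a fixed-width temperature
#' grid, and place each averaged relation on an absolute open-probability
#' scale using the conditions' relative current magnitudes at the reference
#' temperature against the stated reference open probability. Every scaling
#' step is recorded in the returned provenance.
#'
#' @param config list (or path to a JSON file) with blocks:
#'   \describe{
#'     \item{seed}{integer; drives all simulated cells.}
#'     \item{model}{optional path to a gating-model JSON (default: the
#'       illustrative preset).}
#'     \item{conditions}{list of lists with `na` (molar), optional `caps`
#'       (molar) and `label`; the first condition is the scaling reference.}
#'     \item{reference_Po}{absolute open probability of the first condition
#'       at the reference temperature. Default 0.9.}
#'     \item{ref_T_K}{reference temperature, kelvin. Default 295.15.}
#'     \item{conduction_dH}{conduction enthalpy, kcal/mol. Default 9.}
#'     \item{n_cells}{simulated cells per condition. Default 6.}
#'     \item{noise_sd}{instrument noise, pA. Default 0.}
#'     \item{T_bin}{averaging bin width, kelvin. Default 1.}
#'     \item{inactivation}{logical; include the inactivation overlay.
#'       Default `FALSE`.}
#'   }
#' @return List with `relations` (named list of scaled [pot_relation()]s),
#'   `report` (provenance: config hash, seed, per-condition scaling steps),
#'   and `config` (the expanded configuration).
#' @export
run_pot_pipeline <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = FALSE)
  defaults <- list(seed = 1L, model = NULL, reference_Po = 0.9,
                   ref_T_K = 295.15, conduction_dH = 9, n_cells = 6,
                   noise_sd = 0, T_bin = 1, inactivation = FALSE)
  known <- c(names(defaults), "conditions")
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (is.null(config$conditions) || length(config$conditions) < 1)
    stop("config must list at least one condition", call. = FALSE)
  cfg <- utils::modifyList(defaults, config)
  model <- if (is.null(cfg$model)) model_preset_illustrative()
           else read_gating_model(cfg$model)
  cm <- conduction_model(dH = cfg$conduction_dH)
  inact <- if (isTRUE(cfg$inactivation)) inactivation_params() else NULL
  hash <- .config_hash(cfg[setdiff(names(cfg), "model")])

  relations <- list()
  steps <- list()
  ref_cond <- cfg$conditions[[1]]
  for (ci in seq_along(cfg$conditions)) {
    cond <- cfg$conditions[[ci]]
    na <- cond$na %||% 0
    caps <- cond$caps %||% 0
    label <- cond$label %||% sprintf("cond%d", ci)
    cell_data <- lapply(seq_len(cfg$n_cells), function(k) {
      cell_seed <- cfg$seed + 1000L * ci + k
      set.seed(cell_seed + 500000L)  # separate stream for amplitude scatter
      amp <- exp(stats::rnorm(1, 0, 0.2))  # lognormal expression scatter
      sc <- sim_config(seed = cell_seed, model = model,
                       conduction = conduction_model(dH = cfg$conduction_dH),
                       noise_sd = cfg$noise_sd)
      rel <- gen_it_ramp(sc, na = na, caps = caps, inactivation = inact,
                         amplitude_factor = amp)
      # paired same-cell reference measurement: the current ratio at the
      # reference temperature is taken within each cell (as when I-V
      # relations are recorded at the test and reference solutions in the
      # same cell), so expression-level amplitude scatter cancels
      rel_ref <- gen_it_ramp(sc, na = ref_cond$na %||% 0,
                             caps = ref_cond$caps %||% 0,
                             inactivation = inact, amplitude_factor = amp)
      kref <- which.min(abs(rel$T_K - cfg$ref_T_K))
      list(rel = rel, ratio = rel$I[kref] / rel_ref$I[kref])
    })
    ratio <- mean(vapply(cell_data, `[[`, numeric(1), "ratio"))
    pots <- lapply(cell_data, function(cd) {
      pot <- it_to_pot(cd$rel, cm)
      # normalize each cell at the reference temperature before averaging
      kref <- which.min(abs(pot$T_K - cfg$ref_T_K))
      pot_relation(pot$T_K, pot$Po / pot$Po[kref])
    })
    avg <- average_relations(pots, T_bin = cfg$T_bin)
    unscaled <- pot_relation(avg$T_K, avg$value, sem = avg$sem)
    scaled <- scale_pot(unscaled, current_ratio_at_ref = ratio,
                        reference_Po = cfg$reference_Po,
                        ref_T_K = cfg$ref_T_K, condition = label,
                        reference_condition = ref_cond$label %||% "reference")
    relations[[label]] <- scaled
    steps[[label]] <- list(na_M = na, caps_M = caps,
                           current_ratio = ratio,
                           scale_factor = attr(scaled, "scale_ref")$factor)
  }
  list(relations = relations,
       report = list(config_hash = hash, seed = cfg$seed,
                     reference_Po = cfg$reference_Po,
                     ref_T_K = cfg$ref_T_K, scaling = steps),
       config = cfg)
}

#' Predict open-probability surfaces from a model configuration
#'
#' Evaluates a gating model over temperature/Na+/capsaicin grids and
#' (optionally) writes the surface to CSV with provenance.
#'
#' @param config list (or JSON path) with optional `model` (JSON path),
#'   `T_K`, `na_M`, `caps_M` grids and `out` (CSV path).
#' @return List with `surface` (data frame), and `report` (config hash).
#' @export
run_model_predict <- function(config = list()) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  defaults <- list(model = NULL, T_K = seq(278, 330, 0.5), na_M = 0,
                   caps_M = 0, out = NULL)
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg <- utils::modifyList(defaults, config)
  model <- if (is.null(cfg$model)) model_preset_illustrative()
           else read_gating_model(cfg$model)
  surf <- po_surface(model, unlist(cfg$T_K), unlist(cfg$na_M),
                     unlist(cfg$caps_M))
  if (!is.null(cfg$out)) write_po_surface(surf, cfg$out)
  list(surface = surf,
       report = list(config_hash = .config_hash(cfg[setdiff(names(cfg), "model")])))
}
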