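#' Read and write gating-model parameter sets as JSON
#'
#' Model parameter sets are stored as versioned JSON documents with explicit
#' unit annotations. The loader validates positivity of all equilibrium
#' constants and coupling factors (via the model constructors).
#'
#' @param path file path of the JSON document.
#' @return `read_gating_model()` returns an [allosteric_model()];
#'   `write_gating_model()` returns `path` invisibly.
#' @export
#' @examples
#' path <- system.file("extdata", "model_i_illustrative.json",
#'                     package = "thermogate")
#' m <- read_gating_model(path)
read_gating_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(doc$schema) || !identical(doc$schema, "thermogate-model/1"))
    stop("not a thermogate model document (missing/unknown `schema`)",
         call. = FALSE)
  tr <- function(x) thermo_transition(
    dH0 = x$dH0_kcal_mol %||% 0, dS0 = x$dS0_kcal_mol_K,
    dCp = x$dCp_kcal_mol_K %||% 0, T0 = x$T0_K)
  p <- doc$parameters
  allosteric_model(
    L = p$L, J1 = tr(p$J1), J2 = tr(p$J2), D = p$D, E = p$E,
    K1 = p$K1_per_M, F_na = p$F, G = p$G, H = p$H,
    K2 = p$K2_per_M,
    caps = p$caps_couplings %||% list(),
    coop = p$coop_exponent %||% 1.5)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname read_gating_model
#' @param model an [allosteric_model()].
#' @param description free-text note stored in the document (e.g. whether the
#'   parameter set is illustrative rather than experimentally constrained).
#' @export
write_gating_model <- function(model, path, description = NULL) {
  stopifnot(inherits(model, "allosteric_model"))
  tr <- function(x) {
    out <- list(dS0_kcal_mol_K = x$dS0)
    if (x$dCp == 0) out$dH0_kcal_mol <- x$dH0
    else { out$dCp_kcal_mol_K <- x$dCp; out$T0_K <- x$T0 }
    out
  }
  doc <- list(
    schema = "thermogate-model/1",
    description = description,
    units = list(enthalpy = "kcal/mol", entropy = "kcal/(mol K)",
                 temperature = "K", association_constants = "1/M"),
    parameters = list(
      L = model$L, J1 = tr(model$J1), J2 = tr(model$J2),
      D = model$D, E = model$E,
      K1_per_M = model$K1, F = model$F_na, G = model$G, H = model$H,
      K2_per_M = model$K2, caps_couplings = model$caps,
      coop_exponent = model$coop))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Illustrative model-i parameter preset
#'
#' Loads the parameter set shipped with the package
#' (`extdata/model_i_illustrative.json`). The values are *illustrative*, not
#' experimentally fitted: they are chosen so that the model reproduces the
#' qualitative phenomenology of Na+- and capsaicin-modulated heat gating
#' (low-temperature rise, an intermediate open-probability plateau whose level
#' falls and whose width shrinks with external Na+, a steep high-temperature
#' rise, and near-full activation in saturating capsaicin).
#'
#' @return An [allosteric_model()].
#' @export
model_preset_illustrative <- function() {
  read_gating_model(system.file("extdata", "model_i_illustrative.json",
                                package = "thermogate", mustWork = TRUE))
}

#' Open-probability surface over condition grids
#'
#' Evaluates an [allosteric_model()] over the outer grid of temperatures, Na+
#' and capsaicin concentrations.
#'
#' @param model an [allosteric_model()].
#' @param temp temperatures, kelvin.
#' @param na Na+ concentrations, molar.
#' @param caps capsaicin concentrations, molar.
#' @return `data.frame` with columns `T_K`, `na_M`, `caps_M`, `Po`.
#' @export
po_surface <- function(model, temp, na = 0, caps = 0) {
  grid <- expand.grid(T_K = temp, na_M = na, caps_M = caps,
                      KEEP.OUT.ATTRS = FALSE)
  grid$Po <- NA_real_
  for (cond in split(seq_len(nrow(grid)),
                     interaction(grid$na_M, grid$caps_M, drop = TRUE))) {
    grid$Po[cond] <- open_probability(model, grid$T_K[cond],
                                      na = grid$na_M[cond][1],
                                      caps = grid$caps_M[cond][1])
  }
  grid
}

#' Write an open-probability surface to CSV
#'
#' @param surface a data frame from [po_surface()].
#' @param path output CSV path.
#' @export
write_po_surface <- function(surface, path) {
  utils::write.csv(surface, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
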