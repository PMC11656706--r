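#' Model variants
#'
#' The package implements four GUTS (General Unified Threshold model of
#' Survival, stochastic-death) variants that differ in how toxicodynamic
#' damage is represented:
#'
#' * `guts_reduced` — scaled damage driven directly by the external
#'   concentration; fitted to survival data only.
#' * `guts_scaled_damage` — one-compartment toxicokinetics plus a scaled
#'   damage state; fitted to internal concentrations and survival.
#' * `guts_rna` — damage is the *nrf2* fold-change itself, driven by the
#'   internal concentration with first-order reversion to baseline.
#' * `guts_rna_pulse` — threshold-activated *nrf2* expression pulses with a
#'   protein-mediated metabolization feedback on the internal concentration;
#'   the *nrf2* fold-change drives the hazard.
#'
#' @return Character vector of the four variant identifiers.
#' @export
#' @examples
#' guts_variants()
guts_variants <- function() .gp_variants

.check_variant <- function(variant) {
  if (!is.character(variant) || length(variant) != 1 || !variant %in% .gp_variants) {
    abort(paste0(
      "`variant` must be one of ",
      paste0("'", .gp_variants, "'", collapse = ", "), "."
    ))
  }
  variant
}

#' Parameter registry of a model variant
#'
#' Returns the names of the free dynamical (non-error) parameters of a
#' variant, in canonical order, and optionally the error parameters for the
#' endpoints the variant produces.
#'
#' @param variant One of [guts_variants()].
#' @param include_error If `TRUE`, append the log-normal error standard
#'   deviations (`sigma_cint`, `sigma_nrf2`) for endpoints the variant predicts.
#' @return Character vector of parameter names.
#' @export
#' @examples
#' param_registry("guts_rna_pulse")          # 10 parameters
#' param_registry("guts_rna")                # 7 parameters
param_registry <- function(variant, include_error = FALSE) {
  .check_variant(variant)
  core <- switch(variant,
    guts_reduced       = c("k_d", "z", "k_k", "h_b"),
    guts_scaled_damage = c("k_i", "k_e", "k_d", "z", "k_k", "h_b"),
    guts_rna           = c("k_i", "k_e", "k_a", "k_r", "z", "k_k", "h_b"),
    guts_rna_pulse     = c("k_i", "k_m", "z_ci", "v_rt", "r_rt", "k_rd",
                           "k_p", "z", "k_k", "h_b")
  )
  if (include_error) c(core, error_registry(variant)) else core
}

#' @rdname param_registry
#' @export
error_registry <- function(variant) {
  .check_variant(variant)
  switch(variant,
    guts_reduced       = character(0),
    guts_scaled_damage = "sigma_cint",
    guts_rna           = c("sigma_cint", "sigma_nrf2"),
    guts_rna_pulse     = c("sigma_cint", "sigma_nrf2")
  )
}

#' Endpoints predicted by a model variant
#'
#' @inheritParams param_registry
#' @return Character subset of `c("cint", "nrf2", "survival")`.
#' @export
variant_endpoints <- function(variant) {
  .check_variant(variant)
  switch(variant,
    guts_reduced       = "survival",
    guts_scaled_damage = c("cint", "survival"),
    guts_rna           = c("cint", "nrf2", "survival"),
    guts_rna_pulse     = c("cint", "nrf2", "survival")
  )
}

#' Default parameter-sharing map
#'
#' A sharing map flags, for every parameter in the variant registry, whether
#' one common value is fitted across substances (`shared = TRUE`) or one value
#' per substance. The default for `guts_rna_pulse` marks the RNA-protein
#' dynamic and the stochastic-death parameters
#' (`v_rt`, `r_rt`, `k_rd`, `k_p`, `z`, `k_k`, `h_b`) as shared and the
#' toxicokinetic/activation-threshold parameters (`k_i`, `k_m`, `z_ci`) as
#' substance-specific; other variants default to fully substance-specific.
#' Error standard deviations are always shared (endpoint-global).
#'
#' @inheritParams param_registry
#' @param mode `"default"` (the map described above), `"specific"` (nothing
#'   shared), or `"shared"` (everything shared).
#' @return Named logical vector over `param_registry(variant)`; `TRUE` means
#'   shared across substances.
#' @export
#' @examples
#' sharing_map("guts_rna_pulse")
#' sharing_map("guts_rna_pulse", mode = "specific")
sharing_map <- function(variant, mode = c("default", "specific", "shared")) {
  mode <- match.arg(mode)
  reg <- param_registry(variant)
  shared <- switch(mode,
    specific = rep(FALSE, length(reg)),
    shared   = rep(TRUE, length(reg)),
    default  = if (variant == "guts_rna_pulse") {
      reg %in% c("v_rt", "r_rt", "k_rd", "k_p", "z", "k_k", "h_b")
    } else {
      rep(FALSE, length(reg))
    }
  )
  setNames(shared, reg)
}

.check_sharing <- function(variant, sharing) {
  reg <- param_registry(variant)
  if (is.null(names(sharing)) || !setequal(names(sharing), reg) ||
      anyNA(sharing) || !is.logical(sharing)) {
    abort(paste0(
      "`sharing` must be a named logical vector covering exactly the ",
      "registry of '", variant, "': ", paste(reg, collapse = ", ")
    ))
  }
  sharing[reg]
}

#' Count free parameters of a (possibly multi-substance) model
#'
#' Shared parameters are counted once; substance-specific parameters once per
#' substance. The single-substance `guts_rna_pulse` model has 10 dynamical
#' parameters; with three substances the default sharing map gives
#' 7 + 3 x 3 = 16 and the fully substance-specific model 3 x 10 = 30.
#'
#' @inheritParams param_registry
#' @param n_substances Number of substances fitted jointly.
#' @param sharing Named logical sharing map (see [sharing_map()]).
#' @param include_error Count the error standard deviations too (always
#'   shared).
#' @return Integer parameter count.
#' @export
#' @examples
#' count_free_parameters("guts_rna_pulse", 1, sharing_map("guts_rna_pulse", "specific"))
#' count_free_parameters("guts_rna_pulse", 3, sharing_map("guts_rna_pulse"))
count_free_parameters <- function(variant, n_substances,
                                  sharing = sharing_map(variant),
                                  include_error = FALSE) {
  .check_variant(variant)
  stopifnot(is.numeric(n_substances), length(n_substances) == 1, n_substances >= 1)
  sharing <- .check_sharing(variant, sharing)
  n <- sum(sharing) + n_substances * sum(!sharing)
  if (include_error) n <- n + length(error_registry(variant))
  as.integer(n)
}

# ---- parameter validation -------------------------------------------------

# parameters that may be exactly zero (thresholds); all others must be > 0
.gp_zero_ok <- c("z_ci", "z", "h_b", "k_k", "k_m")

#' Validate a parameter vector for a variant
#'
#' Checks that `params` is a named numeric vector covering the variant's
#' registry, finite, strictly positive for rate constants and non-negative
#' for thresholds (`z_ci`, `z`), the killing rate and the background hazard.
#'
#' @inheritParams param_registry
#' @param params Named numeric vector of parameter values (natural scale).
#' @param include_error Require the error standard deviations as well.
#' @return The parameter vector, reordered to registry order, invisibly
#'   usable downstream.
#' @export
validate_params <- function(variant, params, include_error = FALSE) {
  reg <- param_registry(variant, include_error = include_error)
  if (is.list(params)) params <- unlist(params)
  missing <- setdiff(reg, names(params))
  if (length(missing)) {
    abort(paste0("missing parameter(s) for '", variant, "': ",
                 paste(missing, collapse = ", ")))
  }
  p <- params[reg]
  if (any(!is.finite(p))) {
    abort(paste0("non-finite parameter value(s): ",
                 paste(reg[!is.finite(p)], collapse = ", ")))
  }
  lower_ok <- ifelse(reg %in% .gp_zero_ok, p >= 0, p > 0)
  if (any(!lower_ok)) {
    abort(paste0("parameter(s) out of range (must be positive): ",
                 paste(reg[!lower_ok], collapse = ", ")))
  }
  p
}

# ---- configuration files --------------------------------------------------

#' Read and write model configurations
#'
#' A model configuration is a YAML file holding the variant, the per-substance
#' parameter blocks (names exactly as in the registry: `k_i`, `k_m`, `z_ci`,
#' `v_rt`, `r_rt`, `k_rd`, `k_p`, `z`, `k_k`, `h_b`), the error standard
#' deviations and the sharing map. Values round-trip losslessly at full
#' double precision.
#'
#' @param path File path of the YAML configuration.
#' @param config For `write_model_config()`, a list with elements `variant`,
#'   `params` (named list of named parameter vectors, one per substance),
#'   `error_params` (named numeric) and optionally `sharing` (named logical).
#' @return `read_model_config()` returns the validated configuration list.
#' @export
read_model_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$variant)) abort("config is missing a `variant` field")
  .check_variant(cfg$variant)
  cfg$params <- lapply(cfg$params, function(p) {
    validate_params(cfg$variant, unlist(p))
  })
  if (!is.null(cfg$error_params)) {
    cfg$error_params <- unlist(cfg$error_params)
    bad <- !is.finite(cfg$error_params) | cfg$error_params <= 0
    if (any(bad)) abort("error standard deviations must be finite and > 0")
  }
  if (!is.null(cfg$sharing)) {
    cfg$sharing <- .check_sharing(cfg$variant, unlist(cfg$sharing))
  }
  cfg
}

#' @rdname read_model_config
#' @export
write_model_config <- function(config, path) {
  stopifnot(is.list(config), !is.null(config$variant))
  out <- list(
    variant      = config$variant,
    params       = lapply(config$params, as.list),
    error_params = as.list(config$error_params)
  )
  if (!is.null(config$sharing)) out$sharing <- as.list(config$sharing)
  yaml::write_yaml(out, path, precision = 17)
  invisible(path)
}
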