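#' Synthetic study design configuration
#'
#' Describes a multi-endpoint zebrafish-embryo exposure study of the kind the
#' models are built for: several substances, serial-dilution concentration
#' series plus controls, endpoint-specific sampling schedules, and strongly
#' unbalanced endpoint coverage (survival and molecular endpoints never come
#' from the same replicate, so most grid cells are missing).
#'
#' Presets:
#' * `"toy"` — 1 substance, 4 concentrations plus a control, every scheduled
#'   cell observed; fits in seconds.
#' * `"paper_scale"` — 3 substances, 202 treatments, 23 scheduled sampling
#'   occasions across 3 endpoints, realized totals 539 internal-concentration,
#'   169 nrf2 and 233 survival observations (941 in total).
#'
#' @param preset `"toy"` or `"paper_scale"`.
#' @param ... Overrides for any configuration field.
#' @return List of class `gp_design_config` with fields `substances`,
#'   `treatments_per_substance`, `top_conc`, `dilution_factor`, `n_conc`,
#'   `cint_times`, `survival_times`, `nrf2_times`, `n_initial`,
#'   `n_initial_control`, `t_start`, `t_end`, `endpoint_targets`.
#' @export
#' @examples
#' design_config("toy")
design_config <- function(preset = c("toy", "paper_scale"), ...) {
  preset <- match.arg(preset)
  base <- list(
    preset = preset,
    cint_times = c(1.5, 3, 6, 8, 10, 12, 24, 36, 48, 60, 72, 84, 96),
    survival_times = c(24, 48, 72, 96),
    nrf2_times = c(3, 6, 12, 24, 48, 72),
    t_start = 0, t_end = 96,
    # 3 replicates of 3 organisms per treatment; 6 replicates in controls
    n_initial = 9L, n_initial_control = 18L,
    dilution_factor = 2
  )
  cfg <- if (preset == "toy") {
    c(base, list(
      substances = "substance_1",
      treatments_per_substance = 5L,   # 1 control + 4 concentrations
      top_conc = 16, n_conc = 4L,
      endpoint_targets = NULL          # realize every eligible cell
    ))
  } else {
    c(base, list(
      substances = c("substance_1", "substance_2", "substance_3"),
      treatments_per_substance = c(68L, 67L, 67L),
      top_conc = c(16, 8, 32), n_conc = 11L,
      endpoint_targets = c(cint = 539L, nrf2 = 169L, survival = 233L)
    ))
  }
  cfg <- modifyList(cfg, list(...))
  cfg$treatments_per_substance <-
    rep_len(cfg$treatments_per_substance, length(cfg$substances))
  cfg$top_conc <- rep_len(cfg$top_conc, length(cfg$substances))
  bad_t <- c(cfg$cint_times, cfg$survival_times, cfg$nrf2_times)
  if (any(bad_t < cfg$t_start | bad_t > cfg$t_end)) {
    abort("all sampling times must lie within the exposure window")
  }
  structure(cfg, class = "gp_design_config")
}

.endpoint_times <- function(config) {
  list(cint = config$cint_times, nrf2 = config$nrf2_times,
       survival = config$survival_times)
}

#' Generate an exposure design with a missingness mask
#'
#' Enumerates the treatments (per-substance serial dilutions plus controls)
#' and the full treatment x sampling-occasion x endpoint grid, then realizes
#' the configured number of observations per endpoint by stratified
#' subsampling (stratified over sampling times, so every time point keeps
#' coverage). Controls carry no internal-concentration records (the model
#' predicts zero there, below the quantification limit in practice). The
#' result is deterministic given the seed.
#'
#' @param config A [design_config()].
#' @param seed Integer seed for the missingness draw.
#' @return List of class `gp_design` with elements `treatments` (tibble:
#'   `treatment_id`, `substance`, `C_e`, `t_start`, `t_end`, `n_initial`),
#'   `grid` (tibble: `treatment_id`, `endpoint`, `time`, `eligible`,
#'   `realized` — the missingness mask), and `config`.
#' @export
generate_design <- function(config = design_config("toy"), seed = 1L) {
  stopifnot(inherits(config, "gp_design_config"))
  concs <- function(s_idx) {
    # cycle: control, then the serial dilution top, top/f, ...
    series <- c(0, config$top_conc[s_idx] /
                  config$dilution_factor^(seq_len(config$n_conc) - 1))
    rep_len(series, config$treatments_per_substance[s_idx])
  }
  treatments <- purrr::imap_dfr(config$substances, function(sub, i) {
    ce <- concs(i)
    tibble::tibble(
      treatment_id = sprintf("%s_t%02d", sub, seq_along(ce)),
      substance = sub, C_e = ce,
      t_start = config$t_start, t_end = config$t_end,
      n_initial = ifelse(ce == 0, config$n_initial_control, config$n_initial)
    )
  })

  ep_times <- .endpoint_times(config)
  grid <- purrr::imap_dfr(ep_times, function(tt, ep) {
    tidyr::crossing(treatment_id = treatments$treatment_id, time = tt) |>
      dplyr::mutate(endpoint = ep, .after = "treatment_id")
  }) |>
    dplyr::left_join(treatments[c("treatment_id", "C_e")], by = "treatment_id") |>
    dplyr::mutate(eligible = !(.data$endpoint == "cint" & .data$C_e == 0)) |>
    dplyr::select(-"C_e")

  targets <- config$endpoint_targets
  set.seed(seed)
  grid$realized <- grid$eligible
  if (!is.null(targets)) {
    for (ep in names(targets)) {
      cells <- which(grid$endpoint == ep & grid$eligible)
      if (targets[[ep]] > length(cells)) {
        abort(paste0("endpoint target for '", ep, "' (", targets[[ep]],
                     ") exceeds the ", length(cells), " eligible grid cells"))
      }
      grid$realized[cells] <- FALSE
      # proportional allocation over time strata, largest remainder
      strata <- split(cells, grid$time[cells])
      quota <- targets[[ep]] * lengths(strata) / length(cells)
      n_take <- floor(quota)
      rem <- targets[[ep]] - sum(n_take)
      if (rem > 0) {
        order_rem <- order(quota - n_take, decreasing = TRUE)
        n_take[order_rem[seq_len(rem)]] <- n_take[order_rem[seq_len(rem)]] + 1
      }
      for (j in seq_along(strata)) {
        take <- sample(strata[[j]], n_take[j])
        grid$realized[take] <- TRUE
      }
    }
  }
  structure(list(treatments = treatments, grid = grid, config = config,
                 seed = seed),
            class = "gp_design")
}

#' Scenario list from a design
#'
#' @param design A `gp_design` or its `treatments` tibble.
#' @return Named list of [exposure_scenario()] objects keyed by treatment id.
#' @export
scenarios_from_design <- function(design) {
  tr <- if (inherits(design, "gp_design")) design$treatments else tibble::as_tibble(design)
  out <- purrr::pmap(tr, function(treatment_id, substance, C_e, t_start, t_end,
                                  n_initial, ...) {
    exposure_scenario(substance, C_e, t_start, t_end, n_initial,
                      treatment_id = treatment_id)
  })
  setNames(out, tr$treatment_id)
}

#' Design bookkeeping
#'
#' Summarizes the potential-observation grid of a design the way the study
#' design is usually reported: treatments x scheduled sampling occasions x
#' endpoints, with the realized observations and the missing remainder. A
#' "sampling occasion" is one entry of one endpoint's schedule, so the
#' paper-scale preset has 13 + 4 + 6 = 23 occasions.
#'
#' @param design A `gp_design`.
#' @return One-row tibble with `n_treatments`, `n_timepoints`, `n_endpoints`,
#'   `n_grid_cells`, `n_observed`, `n_missing`.
#' @export
#' @examples
#' design_bookkeeping(generate_design(design_config("toy"), seed = 1))
design_bookkeeping <- function(design) {
  stopifnot(inherits(design, "gp_design"))
  ep_times <- .endpoint_times(design$config)
  n_tp <- sum(lengths(ep_times))
  n_tr <- nrow(design$treatments)
  n_ep <- length(ep_times)
  n_obs <- sum(design$grid$realized)
  tibble::tibble(
    n_treatments = n_tr, n_timepoints = n_tp, n_endpoints = n_ep,
    n_grid_cells = n_tr * n_tp * n_ep, n_observed = n_obs,
    n_missing = n_tr * n_tp * n_ep - n_obs
  )
}

# ---- ground truth ---------------------------------------------------------

#' Default generating parameters
#'
#' The ground truth used by the benchmark bundles: a GUTS-RNA-pulse parameter
#' set per substance sharing the RNA-protein dynamic and stochastic-death
#' block (`v_rt`, `r_rt`, `k_rd`, `k_p`, `z`, `k_k`, `h_b`) while uptake,
#' metabolization and the activation threshold (`k_i`, `k_m`, `z_ci`) differ
#' between substances, plus endpoint-global log-normal error scales. Values
#' are chosen to produce realistic dynamics: nrf2 pulses peaking at 2-5 fold
#' change, nrf2 decay on the tens-of-minutes scale, protein turnover on the
#' tens-of-hours scale, and a clear dose-response in survival at the top
#' concentrations.
#'
#' @param substances Substance identifiers (up to three default blocks are
#'   recycled beyond that).
#' @return List of class `gp_truth` with `params` (named list per substance),
#'   `error_params`, `sharing`, `variant`.
#' @export
default_ground_truth <- function(substances = "substance_1") {
  shared <- c(v_rt = 20, r_rt = 5, k_rd = 1.5, k_p = 0.05, z = 2.5,
              k_k = 0.05, h_b = 1e-4)
  specific <- list(
    c(k_i = 0.25, k_m = 0.10, z_ci = 0.15),
    c(k_i = 0.10, k_m = 0.02, z_ci = 0.30),
    c(k_i = 0.05, k_m = 0.05, z_ci = 0.45)
  )
  params <- purrr::imap(setNames(substances, substances), function(sub, i) {
    idx <- (match(sub, substances) - 1) %% length(specific) + 1
    validate_params("guts_rna_pulse", c(specific[[idx]], shared))
  })
  structure(
    list(
      variant = "guts_rna_pulse",
      params = params,
      error_params = c(sigma_cint = 0.3, sigma_nrf2 = 0.3),
      sharing = sharing_map("guts_rna_pulse")
    ),
    class = "gp_truth"
  )
}

# reference C_i_max of a truth on a design: two deterministic passes, the
# first with a generous provisional scale (upper bound without
# metabolization), the second with the pass-1 maximum
.gp_truth_scaling <- function(design, truth) {
  scen <- scenarios_from_design(design)
  tt <- sort(unique(design$grid$time[design$grid$realized]))
  if (!length(tt)) tt <- design$config$survival_times
  ub <- max(purrr::map_dbl(scen, function(sc) {
    p <- truth$params[[sc$substance]]
    ce <- if (is.data.frame(sc$C_e)) max(sc$C_e$C_e) else sc$C_e
    p[["k_i"]] * ce * (sc$t_end - sc$t_start)
  }))
  if (ub <= 0) return(scaling_context(1))
  pass <- function(cimax) {
    max(purrr::map_dbl(scen, function(sc) {
      tr <- simulate_guts(truth$variant, truth$params[[sc$substance]],
                          scaling_context(cimax), sc,
                          times = sort(unique(c(sc$t_start, tt))))
      if ("C_i" %in% names(tr)) max(tr$C_i) else 0
    }))
  }
  scaling_context(pass(pass(ub)))
}

#' Draw noisy observations from a ground truth
#'
#' Generative mirror of the error models: internal concentrations and nrf2
#' fold-changes are drawn log-normally around the deterministic trajectories
#' (log-scale sd `sigma_cint` / `sigma_nrf2`), survivor counts follow the
#' conditional-binomial chain — each realized survival time draws a binomial
#' thinning of the previously realized count with probability
#' `S(t)/S(t_prev)`.
#'
#' @param design A `gp_design` from [generate_design()].
#' @param truth A `gp_truth` (see [default_ground_truth()]).
#' @param seed Integer seed.
#' @param scaling Optional [scaling_context()]; by default a reference
#'   `C_i_max` is derived from the truth's deterministic trajectories.
#' @return List with `observations` (a validated observation table) and
#'   `scaling` (the scaling context used for generation).
#' @export
simulate_observations <- function(design, truth, seed = 1L, scaling = NULL) {
  stopifnot(inherits(design, "gp_design"), inherits(truth, "gp_truth"))
  scaling <- scaling %||% .gp_truth_scaling(design, truth)
  scen <- scenarios_from_design(design)
  realized <- design$grid[design$grid$realized, ]
  set.seed(seed)
  rows <- list()
  for (tid in unique(realized$treatment_id)) {
    cells <- realized[realized$treatment_id == tid, ]
    sc <- scen[[tid]]
    tt <- sort(unique(cells$time))
    tr <- simulate_guts(truth$variant, truth$params[[sc$substance]], scaling,
                        sc, times = sort(unique(c(sc$t_start, tt))))
    at <- function(col, t) tr[[col]][match(t, tr$time)]
    rna_col <- if (truth$variant == "guts_rna_pulse") "R" else "D"

    for (ep in intersect(.gp_endpoints, unique(cells$endpoint))) {
      t_ep <- sort(cells$time[cells$endpoint == ep])
      if (ep == "cint") {
        pred <- at("C_i", t_ep)
        val <- rlnorm(length(t_ep), log(pmax(pred, 1e-12)),
                      truth$error_params[["sigma_cint"]])
        n_risk <- NA_integer_
      } else if (ep == "nrf2") {
        pred <- at(rna_col, t_ep)
        val <- rlnorm(length(t_ep), log(pmax(pred, 1e-12)),
                      truth$error_params[["sigma_nrf2"]])
        n_risk <- NA_integer_
      } else {
        S <- at("S", t_ep)
        n_prev <- sc$n_initial; S_prev <- 1
        val <- integer(length(t_ep))
        for (j in seq_along(t_ep)) {
          p <- min(max(S[j] / S_prev, 0), 1)
          val[j] <- rbinom(1, n_prev, p)
          n_prev <- val[j]; S_prev <- S[j]
        }
        n_risk <- sc$n_initial
      }
      rows[[length(rows) + 1]] <- tibble::tibble(
        treatment_id = tid, substance = sc$substance, endpoint = ep,
        time = t_ep, value = as.numeric(val), n_at_risk = n_risk
      )
    }
  }
  observations <- dplyr::bind_rows(rows)
  .assert_valid_observations(observations)
  list(observations = observations, scaling = scaling)
}

#' Build a benchmark bundle
#'
#' Convenience wrapper tying the design generator and the observation
#' sampler together with a provenance manifest.
#'
#' @param preset `"toy"` or `"paper_scale"` (see [design_config()]).
#' @param seed Master seed; the design mask and the observation noise use
#'   deterministic offsets of it.
#' @param truth Optional `gp_truth`; defaults to [default_ground_truth()] on
#'   the preset's substances.
#' @return List of class `gp_bundle` with `design`, `observations`,
#'   `scaling`, `truth`, `manifest`.
#' @export
#' @examples
#' b <- make_benchmark("toy", seed = 7)
#' design_bookkeeping(b$design)
make_benchmark <- function(preset = c("toy", "paper_scale"), seed = 1L,
                           truth = NULL) {
  preset <- match.arg(preset)
  config <- design_config(preset)
  truth <- truth %||% default_ground_truth(config$substances)
  design <- generate_design(config, seed = seed)
  sim <- simulate_observations(design, truth, seed = seed + 1L)
  structure(
    list(
      design = design, observations = sim$observations, scaling = sim$scaling,
      truth = truth,
      manifest = list(preset = preset, seed = seed,
                      package = "gutspulse",
                      version = as.character(utils::packageVersion("gutspulse")))
    ),
    class = "gp_bundle"
  )
}
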