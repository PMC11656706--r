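#' Validate an observation table
#'
#' The long-format observation table holds one measured value per row, with
#' explicit columns `treatment_id`, `substance`, `endpoint` (one of `cint`,
#' `nrf2`, `survival`), `time` (h post exposure), `value`, and `n_at_risk`
#' (organisms at exposure start; `NA` for the concentration endpoints).
#' Invariants: positive values for the log-normally distributed endpoints,
#' integer survivor counts between 0 and `n_at_risk`, non-increasing survivor
#' counts within a treatment, unique (treatment, endpoint, time) keys.
#'
#' @param observations A data frame as described.
#' @return A tibble of per-record violations (zero rows when the table is
#'   valid); columns `row`, `treatment_id`, `endpoint`, `time`, `problem`.
#' @export
validate_observations <- function(observations) {
  obs <- tibble::as_tibble(observations)
  req <- c("treatment_id", "substance", "endpoint", "time", "value", "n_at_risk")
  missing <- setdiff(req, names(obs))
  if (length(missing)) {
    abort(paste0("observation table is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  probs <- list()
  note <- function(rows, problem) {
    if (!length(rows)) return()
    probs[[length(probs) + 1]] <<- tibble::tibble(
      row = rows, treatment_id = obs$treatment_id[rows],
      endpoint = obs$endpoint[rows], time = obs$time[rows], problem = problem
    )
  }
  note(which(!obs$endpoint %in% .gp_endpoints), "unknown endpoint")
  note(which(!is.finite(obs$time) | obs$time < 0), "negative or non-finite time")
  pos <- obs$endpoint %in% c("cint", "nrf2")
  note(which(pos & (!is.finite(obs$value) | obs$value <= 0)),
       "non-positive value on a log-normal endpoint")
  sv <- obs$endpoint == "survival"
  note(which(sv & (!is.finite(obs$value) | obs$value < 0 |
                     obs$value != round(obs$value))),
       "survivor count not a non-negative integer")
  note(which(sv & (!is.finite(obs$n_at_risk) | obs$value > obs$n_at_risk)),
       "survivor count exceeds n_at_risk")
  key <- paste(obs$treatment_id, obs$endpoint, obs$time)
  note(which(duplicated(key)), "duplicate (treatment, endpoint, time) record")
  # survivor counts must be non-increasing in time within a treatment
  sv_tab <- obs[sv & is.finite(obs$value), ]
  if (nrow(sv_tab)) {
    bad <- sv_tab |>
      dplyr::mutate(.row = which(sv & is.finite(obs$value))) |>
      dplyr::arrange(.data$treatment_id, .data$time) |>
      dplyr::group_by(.data$treatment_id) |>
      dplyr::filter(dplyr::row_number() > 1 &
                      .data$value > dplyr::lag(.data$value)) |>
      dplyr::ungroup()
    note(bad$.row, "survivor count increases over time")
  }
  if (length(probs)) dplyr::bind_rows(probs) else {
    tibble::tibble(row = integer(), treatment_id = character(),
                   endpoint = character(), time = numeric(), problem = character())
  }
}

.assert_valid_observations <- function(observations) {
  v <- validate_observations(observations)
  if (nrow(v)) {
    abort(paste0(
      "invalid observation table (", nrow(v), " violation(s)); first: row ",
      v$row[1], " - ", v$problem[1]
    ))
  }
  invisible(TRUE)
}

#' Log-normal observation log-density
#'
#' Error model for the positive-valued endpoints (internal concentration and
#' *nrf2* fold-change): the observation is log-normal with log-median equal to
#' the log of the deterministic prediction and log-scale `sigma`. The density
#' includes the `1/obs` Jacobian of the log transform.
#'
#' @param obs Observed value(s), > 0.
#' @param pred Model prediction(s), > 0 (the distribution's median).
#' @param sigma Standard deviation on the log scale, > 0.
#' @return Log-density, vectorized over `obs`/`pred`.
#' @export
#' @examples
#' lognormal_loglik(2.0, 2.0, 1)  # -log(2) - 0.5 log(2 pi)
lognormal_loglik <- function(obs, pred, sigma) {
  if (any(!is.finite(obs)) || any(obs <= 0)) abort("`obs` must be finite and > 0")
  if (any(!is.finite(pred)) || any(pred <= 0)) abort("`pred` must be finite and > 0")
  if (any(!is.finite(sigma)) || any(sigma <= 0)) abort("`sigma` must be finite and > 0")
  dlnorm(obs, meanlog = log(pred), sdlog = sigma, log = TRUE)
}

#' Conditional-binomial survival log-likelihood
#'
#' Likelihood for repeated survivor counts of one treatment: survivors at
#' each observation time are binomial given the survivors at the previous
#' observation, with success probability `S(t) / S(t_prev)` from the model's
#' survival curve. Conditioning uses the previous *observed* count, which is
#' the recommended likelihood for small sampling groups observed repeatedly,
#' and is equivalent (up to a data-only constant) to the multinomial
#' death-interval likelihood.
#'
#' @param survivor_counts Integer survivor counts at the observation times,
#'   non-increasing.
#' @param S_model Model survival probabilities at the same times (relative to
#'   exposure start, where S = 1).
#' @param n_initial Organisms at risk at exposure start.
#' @return Log-likelihood (scalar). Survival ratios marginally outside (0, 1]
#'   due to solver round-off are clipped to `[1e-12, 1]`; genuine violations
#'   are counted in the `"clipped"` attribute.
#' @export
#' @examples
#' conditional_binomial_loglik(c(3, 3), c(0.5, 0.25), n_initial = 3)
conditional_binomial_loglik <- function(survivor_counts, S_model, n_initial) {
  n <- survivor_counts
  if (length(n) != length(S_model)) abort("counts and survival probabilities differ in length")
  if (any(!is.finite(n)) || any(n < 0) || any(n != round(n))) {
    abort("`survivor_counts` must be non-negative integers")
  }
  if (any(diff(n) > 0)) abort("`survivor_counts` must be non-increasing over time")
  if (n[1] > n_initial) abort("first count exceeds `n_initial`")
  S_prev <- c(1, head(S_model, -1))
  n_prev <- c(n_initial, head(n, -1))
  ratio <- S_model / S_prev
  clipped <- sum(ratio > 1 + 1e-9 | ratio <= 0)
  ratio <- pmin(pmax(ratio, 1e-12), 1)
  ll <- sum(dbinom(n, size = n_prev, prob = ratio, log = TRUE))
  structure(ll, clipped = clipped)
}

# multinomial death-interval log-likelihood (independent reference
# formulation; used for cross-checks, not in fitting)
.multinomial_survival_loglik <- function(survivor_counts, S_model, n_initial) {
  S <- c(1, S_model)
  n <- c(n_initial, survivor_counts)
  deaths <- -diff(n)
  p_int <- -diff(S)                       # death probability per interval
  p_final <- S[length(S)]
  lgamma(n_initial + 1) - sum(lgamma(deaths + 1)) -
    lgamma(n[length(n)] + 1) +
    sum(deaths * log(pmax(p_int, 1e-300))) +
    n[length(n)] * log(pmax(p_final, 1e-300))
}

#' Joint log-likelihood over a fragmented multi-endpoint table
#'
#' Sums per-record log-densities over all observations under residual
#' independence: log-normal terms for internal concentrations and *nrf2*
#' fold-changes, conditional-binomial chains for survivor counts. Endpoints
#' the data contain but the variant does not predict are an error; missing
#' cells contribute exactly zero. Each treatment's trajectory is solved once
#' at the union of its observation times.
#'
#' @inheritParams batch_simulate
#' @param error_params Named vector with the `sigma_*` entries required by
#'   the variant (see [error_registry()]).
#' @param observations Validated observation table.
#' @param scenarios Named list of [exposure_scenario()] objects covering every
#'   `treatment_id` in the table (or a design tibble from
#'   [generate_design()]).
#' @return Scalar log-likelihood.
#' @export
joint_loglik <- function(variant, params_by_substance, error_params = NULL,
                         observations, scenarios, scaling = NULL,
                         rtol = 1e-7, atol = 1e-9) {
  .check_variant(variant)
  obs <- tibble::as_tibble(observations)
  if (!nrow(obs)) return(0)
  .assert_valid_observations(obs)
  ep_ok <- variant_endpoints(variant)
  bad_ep <- setdiff(unique(obs$endpoint), ep_ok)
  if (length(bad_ep)) {
    abort(paste0("endpoint(s) not predicted by '", variant, "': ",
                 paste(bad_ep, collapse = ", ")))
  }
  err_need <- intersect(
    paste0("sigma_", intersect(unique(obs$endpoint), c("cint", "nrf2"))),
    error_registry(variant)
  )
  if (length(err_need) &&
      (is.null(error_params) || !all(err_need %in% names(error_params)))) {
    abort(paste0("`error_params` must provide: ", paste(err_need, collapse = ", ")))
  }
  scenarios <- .as_scenario_list(scenarios)
  if (!is.list(params_by_substance) || is.null(names(params_by_substance))) {
    subs <- unique(obs$substance)
    params_by_substance <- setNames(rep(list(params_by_substance), length(subs)), subs)
  }

  ctx <- .gp_build_ctx(variant, obs, scenarios)
  .gp_loglik_ctx(ctx, params_by_substance, error_params, scaling,
                 rtol = rtol, atol = atol)
}

# precomputed evaluation context: one entry per treatment with the solver
# grid, the per-endpoint value vectors and their grid positions.  Built once
# per fit so the likelihood hot path carries no table machinery.  When every
# scenario is constant-exposure, treatments are additionally grouped into
# stacked chunks solved as one ODE system per chunk (see the *_n compiled
# right-hand sides); chunks are kept moderate so a stiffness switch to BDF
# stays affordable.
.gp_build_ctx <- function(variant, obs, scenarios, chunk_size = 16L) {
  scenarios <- .as_scenario_list(scenarios)
  treatments <- lapply(unique(obs$treatment_id), function(tid) {
    rows <- obs[obs$treatment_id == tid, ]
    sc <- scenarios[[tid]]
    if (is.null(sc)) abort(paste0("no scenario for treatment '", tid, "'"))
    tt <- sort(unique(rows$time))
    t_grid <- sort(unique(c(sc$t_start, tt)))
    sr <- rows[rows$endpoint == "survival", ]
    sr <- sr[order(sr$time), ]
    list(
      treatment_id = tid, substance = sc$substance,
      segments = .gp_segments(sc), t0 = sc$t_start, t_grid = t_grid,
      idx_cint = match(rows$time[rows$endpoint == "cint"], t_grid),
      val_cint = rows$value[rows$endpoint == "cint"],
      idx_nrf2 = match(rows$time[rows$endpoint == "nrf2"], t_grid),
      val_nrf2 = rows$value[rows$endpoint == "nrf2"],
      idx_surv = match(sr$time, t_grid),
      val_surv = sr$value,
      n_initial = if (nrow(sr)) sr$n_at_risk[1] else NA_integer_
    )
  })
  ctx <- list(variant = variant, treatments = treatments,
              rna_col = if (variant == "guts_rna_pulse") "R" else "D")
  constant <- all(vapply(treatments, function(tr) nrow(tr$segments) == 1L,
                         logical(1)))
  same_t0 <- length(unique(vapply(treatments, `[[`, numeric(1), "t0"))) == 1L
  if (constant && same_t0 && length(treatments) > 1L) {
    idx <- split(seq_along(treatments),
                 ceiling(seq_along(treatments) / chunk_size))
    ctx$chunks <- lapply(idx, function(i) {
      trs <- treatments[i]
      t_union <- sort(unique(unlist(lapply(trs, `[[`, "t_grid"))))
      list(
        members = i,
        t_union = t_union,
        pos = lapply(trs, function(tr) match(tr$t_grid, t_union)),
        C_e = vapply(trs, function(tr) tr$segments$C_e[1], numeric(1)),
        substance = vapply(trs, `[[`, character(1), "substance")
      )
    })
  }
  ctx
}

.gp_symbols_n <- list(
  guts_rna_pulse     = c(init = "gp_init_pulse_n", derivs = "gp_derivs_pulse_n"),
  guts_rna           = c(init = "gp_init_rna_n",   derivs = "gp_derivs_rna_n"),
  guts_scaled_damage = c(init = "gp_init_sd_n",    derivs = "gp_derivs_sd_n"),
  guts_reduced       = c(init = "gp_init_red_n",   derivs = "gp_derivs_red_n")
)

# positional parameter vector for a stacked chunk, padded to the fixed
# buffer length the compiled initializers request
.gp_parms_n <- function(variant, blocks, scaling, C_e) {
  n <- length(C_e)
  per <- switch(variant,
    guts_rna_pulse = unlist(lapply(seq_len(n), function(j) {
      p <- blocks[[j]]
      c(p[["k_i"]], p[["k_m"]], p[["z_ci"]], p[["v_rt"]], p[["r_rt"]],
        p[["k_rd"]], p[["k_p"]], p[["z"]], p[["k_k"]], p[["h_b"]], C_e[j])
    })),
    guts_rna = unlist(lapply(seq_len(n), function(j) {
      p <- blocks[[j]]
      c(p[["k_i"]], p[["k_e"]], p[["k_a"]], p[["k_r"]], p[["z"]],
        p[["k_k"]], p[["h_b"]], C_e[j])
    })),
    guts_scaled_damage = unlist(lapply(seq_len(n), function(j) {
      p <- blocks[[j]]
      c(p[["k_i"]], p[["k_e"]], p[["k_d"]], p[["z"]], p[["k_k"]],
        p[["h_b"]], C_e[j])
    })),
    guts_reduced = unlist(lapply(seq_len(n), function(j) {
      p <- blocks[[j]]
      c(p[["k_d"]], p[["z"]], p[["k_k"]], p[["h_b"]], C_e[j])
    }))
  )
  head_parms <- switch(variant,
    guts_rna_pulse = c(n, scaling$C_i_max, scaling$R_0),
    guts_rna       = c(n, if (is.null(scaling)) 1 else scaling$R_0),
    c(n)
  )
  out <- c(head_parms, per)
  length(out) <- 8192L   # must match GP_MAXP in the compiled code
  out[is.na(out)] <- 0
  out
}

.gp_loglik_ctx <- function(ctx, params_by_substance, error_params, scaling,
                           rtol = 1e-7, atol = 1e-9) {
  variant <- ctx$variant
  sym <- .gp_symbols[[variant]]
  state0 <- .gp_initial_state(variant, scaling)
  n_state <- length(state0)
  i_H <- n_state                       # H is always the last state
  i_cint <- match("C_i", names(state0))
  i_rna <- match(if (variant == "guts_rna_pulse") "R" else "D", names(state0))

  term_for <- function(tr, m) {
    # m: states at tr$t_grid rows (columns = state variables)
    total <- 0
    if (length(tr$idx_cint)) {
      pred <- pmax(m[tr$idx_cint, i_cint], 1e-12)
      total <- total +
        sum(lognormal_loglik(tr$val_cint, pred, error_params[["sigma_cint"]]))
    }
    if (length(tr$idx_nrf2)) {
      pred <- pmax(m[tr$idx_nrf2, i_rna], 1e-12)
      total <- total +
        sum(lognormal_loglik(tr$val_nrf2, pred, error_params[["sigma_nrf2"]]))
    }
    if (length(tr$idx_surv)) {
      S <- exp(-pmax(0, m[tr$idx_surv, i_H]))
      total <- total + as.numeric(conditional_binomial_loglik(
        tr$val_surv, S, n_initial = tr$n_initial
      ))
    }
    total
  }

  if (!is.null(ctx$chunks)) {
    sym_n <- .gp_symbols_n[[variant]]
    total <- 0
    for (ch in ctx$chunks) {
      n_sys <- length(ch$members)
      blocks <- lapply(ch$substance, function(s) {
        blk <- params_by_substance[[s]]
        if (is.null(blk)) abort(paste0("no parameter block for substance '", s, "'"))
        blk
      })
      y0 <- rep(unname(state0), n_sys)
      sol <- deSolve::lsoda(
        y0, ch$t_union, func = sym_n[["derivs"]],
        parms = .gp_parms_n(variant, blocks, scaling, ch$C_e),
        dllname = "gutspulse", initfunc = sym_n[["init"]],
        rtol = rtol, atol = atol
      )
      di <- attr(sol, "istate")
      if (!is.null(di) && di[1] < 0) abort("stacked solver failed")
      for (j in seq_len(n_sys)) {
        tr <- ctx$treatments[[ch$members[j]]]
        cols <- 1 + (j - 1) * n_state + seq_len(n_state)
        m <- sol[ch$pos[[j]], cols, drop = FALSE]
        total <- total + term_for(tr, m)
      }
    }
    return(total)
  }

  total <- 0
  for (tr in ctx$treatments) {
    blk <- params_by_substance[[tr$substance]]
    if (is.null(blk)) {
      abort(paste0("no parameter block for substance '", tr$substance, "'"))
    }
    segs <- tr$segments
    y <- state0
    m <- matrix(NA_real_, length(tr$t_grid), n_state)
    m[1, ] <- y
    for (k in seq_len(nrow(segs))) {
      keep <- tr$t_grid >= segs$t0[k] & tr$t_grid <= segs$t1[k]
      tt <- sort(unique(c(segs$t0[k], tr$t_grid[keep], segs$t1[k])))
      sol <- deSolve::lsoda(
        y, tt, func = sym[["derivs"]],
        parms = .gp_parms(variant, blk, scaling, segs$C_e[k]),
        dllname = "gutspulse", initfunc = sym[["init"]],
        rtol = rtol, atol = atol
      )
      di <- attr(sol, "istate")
      if (!is.null(di) && di[1] < 0) {
        abort(paste0("solver failed for treatment '", tr$treatment_id, "'"))
      }
      y <- sol[nrow(sol), -1]
      pos <- match(tr$t_grid[keep], sol[, 1])
      m[keep, ] <- sol[pos, -1, drop = FALSE]
    }
    total <- total + term_for(tr, m)
  }
  total
}

# accept a named list of gp_scenario or a design tibble
.as_scenario_list <- function(scenarios) {
  if (is.data.frame(scenarios)) scenarios <- scenarios_from_design(scenarios)
  if (!is.list(scenarios)) abort("`scenarios` must be a list or design table")
  if (is.null(names(scenarios)) || !all(nzchar(names(scenarios)))) {
    names(scenarios) <- vapply(scenarios, `[[`, character(1), "treatment_id")
  }
  scenarios
}

#' Bayesian information criterion
#'
#' `BIC = k log(n) - 2 log L_max`, where `n` is the total observation count of
#' the fitted data subset (all endpoints pooled) and `k` the number of free
#' parameters. Lower is better; comparisons are only meaningful at identical
#' `n`.
#'
#' @param loglik_max Maximized log-likelihood.
#' @param k_params Number of free parameters, >= 1.
#' @param n_obs Number of observations, >= 1.
#' @return BIC value.
#' @export
#' @examples
#' bic(0, 16, 941)  # 16 log(941)
bic <- function(loglik_max, k_params, n_obs) {
  stopifnot(is.finite(loglik_max), k_params >= 1, n_obs >= 1)
  k_params * log(n_obs) - 2 * loglik_max
}
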