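#' Default log-normal priors
#'
#' Uninformative log-normal priors with 2 standard deviations on the log
#' scale, with log-medians at per-parameter plausibility anchors: uptake and
#' elimination rates on the 0.01-1 per-hour scale, nrf2 decay near
#' log(2)/(20 min) (transcript half-lives of 10-20 min), protein turnover
#' near log(2)/(24 h), thresholds near the observed fold-change scale, and a
#' small background hazard. All anchors are overridable.
#'
#' @inheritParams param_registry
#' @param log_sd Prior standard deviation on the log scale (default 2).
#' @param overrides Named numeric vector of replacement log-medians on the
#'   natural scale (values, not logs).
#' @return Tibble with columns `param`, `median`, `logmedian`, `logsd`
#'   covering `param_registry(variant, include_error = TRUE)`.
#' @export
#' @examples
#' default_priors("guts_rna_pulse")
default_priors <- function(variant, log_sd = 2, overrides = NULL) {
  anchors <- c(
    k_i = 0.1, k_m = 0.05, z_ci = 0.25, v_rt = 10, r_rt = 1,
    k_rd = log(2) / (20 / 60), k_p = log(2) / 24, z = 2, k_k = 0.02,
    h_b = 1e-3, k_e = 0.05, k_d = 0.05, k_a = 0.1, k_r = 0.2,
    sigma_cint = 0.3, sigma_nrf2 = 0.3
  )
  if (!is.null(overrides)) anchors[names(overrides)] <- overrides
  reg <- param_registry(variant, include_error = TRUE)
  tibble::tibble(
    param = reg,
    median = unname(anchors[reg]),
    logmedian = log(unname(anchors[reg])),
    logsd = log_sd
  )
}

# ---- free-parameter bookkeeping ------------------------------------------

# one row per free parameter of a (variant, substances, sharing) model:
# columns param, substance (NA when shared), name (unique label)
.free_param_table <- function(variant, substances, sharing, priors) {
  sharing <- .check_sharing(variant, sharing)
  reg <- param_registry(variant)
  rows <- purrr::map_dfr(reg, function(p) {
    if (sharing[[p]] || length(substances) == 1) {
      tibble::tibble(param = p, substance = NA_character_, name = p)
    } else {
      tibble::tibble(param = p, substance = substances,
                     name = paste0(p, "[", substances, "]"))
    }
  })
  err <- error_registry(variant)
  if (length(err)) {
    rows <- dplyr::bind_rows(rows, tibble::tibble(
      param = err, substance = NA_character_, name = err
    ))
  }
  pr <- dplyr::left_join(rows, priors, by = "param")
  if (anyNA(pr$logmedian) || anyNA(pr$logsd)) {
    abort("`priors` must provide a log-normal prior for every free parameter")
  }
  pr
}

# theta (log scale, fpt order) -> list(params_by_substance, error_params)
.unpack_theta <- function(theta, fpt, variant, substances) {
  val <- exp(theta)
  err <- error_registry(variant)
  reg <- param_registry(variant)
  params <- lapply(setNames(substances, substances), function(sub) {
    idx <- vapply(reg, function(p) {
      i <- which(fpt$param == p & (is.na(fpt$substance) | fpt$substance == sub))
      i[1]
    }, integer(1))
    setNames(val[idx], reg)
  })
  error_params <- if (length(err)) {
    setNames(val[match(err, fpt$param)], err)
  } else NULL
  list(params_by_substance = params, error_params = error_params)
}

#' Transform unit-interval draws to initial parameter values
#'
#' Multi-start initial values are drawn from a uniform interval from -1 to 1
#' and transformed to the prior's log-normal scale: a coordinate `u` maps to
#' `exp(logmedian + u * logsd)`, so `u = 0` is the prior median and +/-1 are
#' one prior log-sd away. This is a bounded initializer, not a prior draw —
#' its push-forward is narrower than the prior by construction.
#'
#' @param u Numeric vector in `[-1, 1]`, one entry per free parameter.
#' @param priors Tibble with columns `logmedian`, `logsd` (row order defines
#'   the mapping), e.g. from [default_priors()].
#' @return Named numeric vector of natural-scale parameter values.
#' @export
#' @examples
#' init_from_unit_interval(c(0, 1), default_priors("guts_reduced")[1:2, ])
init_from_unit_interval <- function(u, priors) {
  if (any(!is.finite(u)) || any(abs(u) > 1)) {
    abort("`u` must lie in [-1, 1]")
  }
  if (length(u) != nrow(priors)) abort("`u` length must match the prior rows")
  nm <- if ("name" %in% names(priors)) priors[["name"]] else priors[["param"]]
  setNames(exp(priors$logmedian + u * priors$logsd), nm)
}

# ---- engines --------------------------------------------------------------

# adaptive random-walk Metropolis on the log-parameter scale with
# covariance adaptation during warmup (Haario-style: the proposal
# covariance tracks the running posterior covariance, the global scale is
# tuned toward a 0.234 acceptance rate by Robbins-Monro) and optional
# parallel tempering (n_temps chains with likelihood-tempered targets and
# adjacent-swap moves; the cold chain is recorded).  Heavy-tailed
# multivariate-t proposals help traverse the likelihood ridges typical of
# threshold-activation parameters.
# logpost must return the log posterior with attribute "loglik".
.gp_mcmc <- function(logpost, theta0, warmup = 300L, draws = 500L,
                     thin = 1L, prop_sd = NULL, target_accept = 0.234,
                     n_temps = 1L, temp_factor = 3) {
  d <- length(theta0)
  prop_sd <- prop_sd %||% rep(0.2, d)
  betas <- temp_factor^(-(seq_len(n_temps) - 1))
  # per-chain state: position, log-prior, log-likelihood, adaptation
  chains <- lapply(seq_len(n_temps), function(k) {
    v <- logpost(theta0)
    list(theta = theta0, lprior = as.numeric(v) - attr(v, "loglik"),
         ll = attr(v, "loglik"), log_scale = 0,
         run_mean = theta0, run_cov = diag(prop_sd^2, d),
         L = diag(prop_sd, d))
  })
  best <- as.numeric(chains[[1]]$lprior + chains[[1]]$ll)
  out <- matrix(NA_real_, draws, d, dimnames = list(NULL, names(theta0)))
  lp_out <- numeric(draws)
  acc <- 0L
  total <- warmup + draws * thin
  adapt_from <- max(20L, d * 2L)
  for (i in seq_len(total)) {
    for (k in seq_len(n_temps)) {
      ch <- chains[[k]]
      g <- sqrt(stats::rchisq(1, df = 4) / 4)
      cand <- ch$theta + exp(ch$log_scale) * as.numeric(ch$L %*% rnorm(d)) / g
      v <- logpost(cand)
      ll_cand <- attr(v, "loglik")
      lprior_cand <- as.numeric(v) - ll_cand
      lp_old <- ch$lprior + betas[k] * ch$ll
      lp_new <- lprior_cand + betas[k] * ll_cand
      accept <- is.finite(lp_new) && log(runif(1)) < lp_new - lp_old
      if (accept) {
        ch$theta <- cand; ch$lprior <- lprior_cand; ch$ll <- ll_cand
        if (k == 1L) {
          acc <- acc + 1L
          if (lprior_cand + ll_cand > best) best <- lprior_cand + ll_cand
        }
      }
      if (i <= warmup) {
        rate <- min(1, exp(lp_new - lp_old))
        if (!is.finite(rate)) rate <- 0
        ch$log_scale <- ch$log_scale + (rate - target_accept) / sqrt(i) * 2
        dlt <- ch$theta - ch$run_mean
        ch$run_mean <- ch$run_mean + dlt / (i + 1)
        ch$run_cov <- ch$run_cov * (i / (i + 1)) +
          tcrossprod(dlt) * (i / (i + 1)^2)
        if (i >= adapt_from && i %% 20 == 0) {
          sigma <- (2.38^2 / d) * ch$run_cov + 1e-8 * diag(d)
          chol_s <- tryCatch(chol(sigma), error = function(e) NULL)
          if (!is.null(chol_s)) {
            ch$L <- t(chol_s)
            ch$log_scale <- 0
          }
        }
      }
      chains[[k]] <- ch
    }
    if (n_temps > 1L) {
      # one adjacent-temperature swap proposal per sweep
      k <- sample.int(n_temps - 1L, 1L)
      a <- chains[[k]]; b <- chains[[k + 1L]]
      log_r <- (betas[k] - betas[k + 1L]) * (b$ll - a$ll)
      if (is.finite(log_r) && log(runif(1)) < log_r) {
        sw <- c("theta", "lprior", "ll")
        tmp <- a[sw]; a[sw] <- b[sw]; b[sw] <- tmp
        chains[[k]] <- a; chains[[k + 1L]] <- b
        if (k == 1L) {
          lp1 <- chains[[1]]$lprior + chains[[1]]$ll
          if (is.finite(lp1) && lp1 > best) best <- lp1
        }
      }
    }
    if (i > warmup && (i - warmup) %% thin == 0) {
      out[(i - warmup) %/% thin, ] <- chains[[1]]$theta
      lp_out[(i - warmup) %/% thin] <- chains[[1]]$lprior + chains[[1]]$ll
    }
  }
  list(draws = out, logpost = lp_out, loss = -best,
       accept_rate = acc / total, endpoint = chains[[1]]$theta,
       converged = TRUE)
}

# mean-field Gaussian approximation: mode finding (BFGS) followed by
# ELBO-based scale calibration with common random numbers
.gp_svi <- function(logpost, theta0, draws = 500L, maxit_mode = 200L,
                    maxit_scale = 120L, n_elbo = 4L) {
  d <- length(theta0)
  neg <- function(th) {
    v <- logpost(th)
    if (!is.finite(v)) 1e10 else -as.numeric(v)
  }
  opt <- optim(theta0, neg, method = "BFGS",
               control = list(maxit = maxit_mode, reltol = 1e-10))
  m <- opt$par
  # diagonal curvature for initial scales
  h <- vapply(seq_len(d), function(j) {
    eps <- 1e-3 * max(1, abs(m[j]))
    e <- rep(0, d); e[j] <- eps
    (neg(m + e) - 2 * opt$value + neg(m - e)) / eps^2
  }, numeric(1))
  s0 <- ifelse(is.finite(h) & h > 0, 1 / sqrt(h), 0.5)
  s0 <- pmin(pmax(s0, 1e-3), 2)
  eps_mat <- matrix(rnorm(n_elbo * d), n_elbo, d)
  elbo <- function(log_s) {
    s <- exp(log_s)
    e_lp <- mean(vapply(seq_len(n_elbo), function(k) {
      v <- logpost(m + s * eps_mat[k, ])
      if (!is.finite(v)) -1e10 else as.numeric(v)
    }, numeric(1)))
    e_lp + sum(log_s)                     # entropy up to an additive constant
  }
  opt_s <- optim(log(s0), function(ls) -elbo(ls),
                 method = if (d == 1) "BFGS" else "Nelder-Mead",
                 control = list(maxit = maxit_scale))
  s <- exp(opt_s$par)
  out <- matrix(rnorm(draws * d), draws, d, dimnames = list(NULL, names(theta0)))
  out <- sweep(sweep(out, 2, s, `*`), 2, m, `+`)
  list(draws = out, logpost = rep(NA_real_, draws),
       loss = opt_s$value,                  # negative ELBO, constant dropped
       accept_rate = NA_real_, endpoint = m,
       converged = opt$convergence == 0)
}

# ---- multistart fit -------------------------------------------------------

#' Multi-start Bayesian fit
#'
#' Fits a model variant to an observation table. The log-posterior over the
#' free parameters (log scale) combines the joint likelihood with the
#' log-normal priors. `n_starts` estimations are launched from initial values
#' drawn from a uniform interval from -1 to 1 and transformed to the prior
#' scale ([init_from_unit_interval()]). Every start runs a deterministic
#' local estimation (a simplex search polished by quasi-Newton steps); the
#' optimized negative log-posterior is the start's recorded loss and its end
#' point feeds the identifiability diagnostics
#' ([detect_posterior_clusters()]). The best-loss start is then promoted to
#' seed the posterior engine: adaptive-covariance random-walk Metropolis
#' (`"mcmc"`) or a mean-field Gaussian approximation (`"variational"`).
#' Reruns with the same seed reproduce the recorded summaries exactly.
#'
#' @inheritParams joint_loglik
#' @param observations Validated observation table.
#' @param sharing Named logical sharing map (see [sharing_map()]).
#' @param priors Prior table from [default_priors()] (or same columns).
#' @param n_starts Number of multi-start launches (the study design uses
#'   100; reduce for quick fits).
#' @param seed Master seed; per-start substreams are derived from it.
#' @param engine `"mcmc"` (adaptive random-walk Metropolis) or
#'   `"variational"` (mean-field Gaussian approximation).
#' @param draws Posterior draws kept from the promoted start.
#' @param warmup Warmup iterations for the MCMC engine.
#' @param thin Thinning interval of the MCMC engine: `draws * thin`
#'   post-warmup iterations are run and every `thin`-th state is kept.
#' @param n_temps Number of parallel-tempering chains for the MCMC engine
#'   (1 = plain adaptive Metropolis). Tempered chains help the sampler cross
#'   between the near-equivalent modes that threshold-activation models
#'   produce.
#' @param opt_maxit Iteration budget of each start's simplex search (a tenth
#'   of it for the quasi-Newton polish).
#' @return Object of class `gp_fit`: posterior draws (tibble), per-start
#'   losses, BIC, provenance. Methods: [tidy()], [glance()], [autoplot()].
#' @export
multistart_fit <- function(variant, observations, scenarios, scaling = NULL,
                           sharing = sharing_map(variant),
                           priors = default_priors(variant),
                           n_starts = 100L, seed = 1L,
                           engine = c("mcmc", "variational"),
                           draws = 500L, warmup = 300L, thin = 1L,
                           n_temps = 1L, opt_maxit = 600L,
                           rtol = 1e-6, atol = 1e-8) {
  engine <- match.arg(engine)
  .check_variant(variant)
  obs <- tibble::as_tibble(observations)
  .assert_valid_observations(obs)
  scenarios <- .as_scenario_list(scenarios)
  substances <- sort(unique(obs$substance))
  if (is.null(scaling) && variant %in% c("guts_rna", "guts_rna_pulse")) {
    scaling <- compute_scaling(obs)
  }
  fpt <- .free_param_table(variant, substances, sharing, priors)
  d <- nrow(fpt)
  n_obs <- nrow(obs)

  # validate once, then evaluate through a precomputed context
  ep_ok <- variant_endpoints(variant)
  bad_ep <- setdiff(unique(obs$endpoint), ep_ok)
  if (length(bad_ep)) {
    abort(paste0("endpoint(s) not predicted by '", variant, "': ",
                 paste(bad_ep, collapse = ", ")))
  }
  ctx <- .gp_build_ctx(variant, obs, scenarios)

  loglik_max <- -Inf
  logpost <- function(theta) {
    pk <- .unpack_theta(theta, fpt, variant, substances)
    ll <- tryCatch(
      suppressWarnings(
        .gp_loglik_ctx(ctx, pk$params_by_substance, pk$error_params,
                       scaling, rtol = rtol, atol = atol)
      ),
      error = function(e) -Inf
    )
    if (is.finite(ll) && ll > loglik_max) loglik_max <<- ll
    lp <- ll + sum(dnorm(theta, fpt$logmedian, fpt$logsd, log = TRUE))
    structure(lp, loglik = ll)
  }
  neg_lp <- function(theta) {
    v <- logpost(theta)
    if (!is.finite(v)) 1e10 else -as.numeric(v)
  }

  set.seed(seed)
  u_mat <- matrix(runif(n_starts * d, -1, 1), n_starts, d)
  start_seeds <- sample.int(.Machine$integer.max - 1L, n_starts)

  # phase 1 — every start runs a deterministic local estimation (simplex
  # then quasi-Newton polish) and is ranked by its optimized loss
  starts <- vector("list", n_starts)
  for (s in seq_len(n_starts)) {
    theta0 <- setNames(fpt$logmedian + u_mat[s, ] * fpt$logsd, fpt$name)
    o <- optim(theta0, neg_lp, method = "Nelder-Mead",
               control = list(maxit = opt_maxit))
    o <- tryCatch(
      optim(o$par, neg_lp, method = "BFGS",
            control = list(maxit = ceiling(opt_maxit / 10))),
      error = function(e) o
    )
    starts[[s]] <- tibble::tibble(
      start = s, loss = o$value, converged = o$convergence == 0,
      endpoint = list(setNames(o$par, fpt$name))
    )
  }
  starts <- dplyr::bind_rows(starts)
  if (all(starts$loss >= 1e10)) {
    abort(paste0("all ", n_starts, " starts diverged; losses: ",
                 paste(signif(starts$loss, 3), collapse = ", ")))
  }
  best <- which.min(starts$loss)

  # phase 2 — the promoted start seeds the posterior engine
  theta_best <- starts$endpoint[[best]]
  set.seed(start_seeds[best])
  best_run <- if (engine == "mcmc") {
    .gp_mcmc(logpost, theta_best, warmup = warmup, draws = draws,
             thin = thin, n_temps = n_temps,
             prop_sd = pmin(fpt$logsd, 1) * 0.05)
  } else {
    .gp_svi(logpost, theta_best, draws = draws, maxit_mode = 50L)
  }
  draws_tbl <- tibble::as_tibble(as.data.frame(best_run$draws))
  names(draws_tbl) <- fpt$name
  draws_tbl <- dplyr::mutate(draws_tbl,
                             .draw = dplyr::row_number(), .before = 1)

  k <- count_free_parameters(variant, length(substances), sharing,
                             include_error = TRUE)
  structure(
    list(
      variant = variant, engine = engine, sharing = sharing,
      substances = substances, fpt = fpt, priors = priors,
      draws = draws_tbl, starts = starts, best_start = best,
      loglik_max = loglik_max, k = k, n_obs = n_obs,
      bic = bic(loglik_max, k, n_obs),
      scaling = scaling, scenarios = scenarios,
      data_fingerprint = .gp_fingerprint(obs),
      seed = seed, n_starts = n_starts
    ),
    class = "gp_fit"
  )
}

.gp_fingerprint <- function(obs) {
  o <- obs[order(obs$treatment_id, obs$endpoint, obs$time), ]
  rlang::hash(list(o$treatment_id, o$endpoint, o$time, round(o$value, 12)))
}

#' @export
print.gp_fit <- function(x, ...) {
  cat("<gp_fit> ", x$variant, " | engine: ", x$engine,
      " | k = ", x$k, " free parameters\n", sep = "")
  cat("  substances: ", paste(x$substances, collapse = ", "), "\n", sep = "")
  cat("  n_obs = ", x$n_obs, ", n_starts = ", x$n_starts,
      " (best: ", x$best_start, ")\n", sep = "")
  cat("  max log-likelihood = ", signif(x$loglik_max, 6),
      ", BIC = ", signif(x$bic, 6), "\n", sep = "")
  invisible(x)
}

#' Tidy posterior summaries of a fit
#'
#' @param x A `gp_fit`.
#' @param conf_level Credible-interval mass (default 0.95).
#' @param ... Unused.
#' @return Tibble with one row per free parameter: posterior median, mean,
#'   sd, and equal-tailed credible bounds on the natural scale.
#' @export
tidy.gp_fit <- function(x, conf_level = 0.95, ...) {
  a <- (1 - conf_level) / 2
  x$draws |>
    tidyr::pivot_longer(-".draw", names_to = "term", values_to = "log_value") |>
    dplyr::group_by(.data$term) |>
    dplyr::summarise(
      estimate = exp(median(.data$log_value)),
      mean = mean(exp(.data$log_value)),
      std.error = sd(exp(.data$log_value)),
      conf.low = exp(quantile(.data$log_value, a)),
      conf.high = exp(quantile(.data$log_value, 1 - a)),
      .groups = "drop"
    ) |>
    dplyr::arrange(match(.data$term, x$fpt$name))
}

#' One-row fit summary
#'
#' @param x A `gp_fit`.
#' @param ... Unused.
#' @return Tibble with variant, engine, parameter count, observation count,
#'   maximum log-likelihood, BIC and provenance.
#' @export
glance.gp_fit <- function(x, ...) {
  tibble::tibble(
    variant = x$variant, engine = x$engine, k = x$k, n_obs = x$n_obs,
    loglik_max = x$loglik_max, bic = x$bic,
    n_starts = x$n_starts, best_start = x$best_start, seed = x$seed
  )
}

# ---- posterior trajectory envelopes ---------------------------------------

#' Credible-interval trajectory envelopes
#'
#' Pointwise quantiles of the deterministic trajectories over posterior
#' parameter draws. Residual (predictive) error is deliberately excluded:
#' the envelopes reflect parametric uncertainty of the deterministic model
#' only.
#'
#' @param fit A `gp_fit`.
#' @param scenario An [exposure_scenario()].
#' @param level Credible mass (default 0.95; `1` gives the min/max envelope).
#' @param times Output grid; defaults to 97 points over the scenario window.
#' @param max_draws Cap on the number of draws propagated (thinned evenly).
#' @return Tibble with `time`, `variable`, `lower`, `median`, `upper`.
#' @export
posterior_trajectory_bci <- function(fit, scenario, level = 0.95,
                                     times = NULL, max_draws = 200L) {
  stopifnot(inherits(fit, "gp_fit"))
  if (nrow(fit$draws) < 1) abort("fit has no posterior draws")
  times <- times %||% seq(scenario$t_start, scenario$t_end, length.out = 97)
  idx <- unique(round(seq(1, nrow(fit$draws),
                          length.out = min(max_draws, nrow(fit$draws)))))
  trajs <- purrr::map(idx, function(i) {
    theta <- as.numeric(fit$draws[i, fit$fpt$name])
    pk <- .unpack_theta(theta, fit$fpt, fit$variant, fit$substances)
    simulate_guts(fit$variant, pk$params_by_substance[[scenario$substance]],
                  fit$scaling, scenario, times = times)
  })
  vars <- setdiff(names(trajs[[1]]), "time")
  a <- (1 - level) / 2
  purrr::map_dfr(vars, function(v) {
    m <- vapply(trajs, function(tr) tr[[v]], numeric(length(times)))
    m <- matrix(m, nrow = length(times))
    tibble::tibble(
      time = times, variable = v,
      lower = apply(m, 1, quantile, probs = a),
      median = apply(m, 1, quantile, probs = 0.5),
      upper = apply(m, 1, quantile, probs = 1 - a)
    )
  })
}

# ---- identifiability diagnostics ------------------------------------------

#' Detect clusters of multi-start end points
#'
#' Multi-start estimation of overparameterized ODE models often converges to
#' multiple clusters of parameter values with very similar likelihood — the
#' classical identifiability symptom. This diagnostic groups the per-start
#' end points in log-parameter space by density-based single-linkage merging:
#' points closer than `eps` (in log units, i.e. relative parameter
#' differences) join a cluster. The default radius of 0.3 log units treats
#' estimates within roughly 35% of each other as one mode; genuine
#' identifiability clusters typically sit orders of magnitude apart.
#'
#' @param x A `gp_fit`, or a numeric matrix / data frame of end points
#'   (rows = starts, columns = log-parameters).
#' @param parameters Optional character vector restricting the parameter
#'   axes (e.g. a pair such as `c("k_k", "r_rt")`).
#' @param eps Merge radius in log-parameter units (default 0.3).
#' @param losses Optional per-start losses (taken from the fit when `x` is a
#'   `gp_fit`).
#' @return List with `labels` (integer cluster id per start) and `clusters`
#'   (tibble: cluster, n, loss_min, loss_median, loss_max).
#' @export
detect_posterior_clusters <- function(x, parameters = NULL, eps = 0.3,
                                      losses = NULL) {
  if (inherits(x, "gp_fit")) {
    losses <- losses %||% x$starts$loss
    m <- do.call(rbind, x$starts$endpoint)
  } else {
    m <- as.matrix(x)
  }
  if (!is.null(parameters)) m <- m[, parameters, drop = FALSE]
  if (nrow(m) < 1) abort("no end points to cluster")
  labels <- if (nrow(m) == 1) {
    1L
  } else {
    hc <- hclust(dist(m), method = "single")
    as.integer(cutree(hc, h = eps + 1e-12))
  }
  losses <- losses %||% rep(NA_real_, nrow(m))
  clusters <- tibble::tibble(cluster = labels, loss = losses) |>
    dplyr::group_by(.data$cluster) |>
    dplyr::summarise(
      n = dplyr::n(), loss_min = min(.data$loss),
      loss_median = median(.data$loss), loss_max = max(.data$loss),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$loss_min)
  list(labels = labels, clusters = clusters)
}

# ---- model comparison ------------------------------------------------------

#' Compare fitted models by BIC
#'
#' All fits must be to the same observation table (checked via a data
#' fingerprint, so `n` is identical across rows). Sorted by BIC ascending;
#' `delta_bic` is relative to the best model.
#'
#' @param ... `gp_fit` objects, or a single list of them (optionally named).
#' @return Tibble: `model`, `variant`, `engine`, `k`, `n_obs`, `loglik_max`,
#'   `bic`, `delta_bic`.
#' @export
compare_models <- function(...) {
  fits <- list(...)
  if (length(fits) == 1 && is.list(fits[[1]]) && !inherits(fits[[1]], "gp_fit")) {
    fits <- fits[[1]]
  }
  if (!length(fits) || !all(vapply(fits, inherits, logical(1), "gp_fit"))) {
    abort("`compare_models()` expects gp_fit objects")
  }
  fps <- vapply(fits, `[[`, character(1), "data_fingerprint")
  if (length(unique(fps)) > 1) {
    abort("fits were made to different observation tables; BIC is not comparable")
  }
  nm <- names(fits) %||% rep("", length(fits))
  nm[!nzchar(nm)] <- paste0("model_", seq_along(fits))[!nzchar(nm)]
  tbl <- purrr::map2_dfr(fits, nm, function(f, n) {
    dplyr::mutate(glance(f), model = n, .before = 1)
  }) |>
    dplyr::select("model", "variant", "engine", "k", "n_obs",
                  "loglik_max", "bic") |>
    dplyr::arrange(.data$bic) |>
    dplyr::mutate(delta_bic = .data$bic - .data$bic[1])
  tbl
}
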