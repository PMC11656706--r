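#' Threshold activation of nrf2 expression
#'
#' Sigmoid activation of the constant *nrf2* expression rate as a function of
#' the scaled internal concentration. The default is the logistic
#' \deqn{A(c) = \frac{1}{1 + e^{-v_{rt}(c - z_{ci})}}}{A(c) = 1/(1+exp(-v_rt (c - z_ci)))}
#' which is 0.5 exactly at the threshold `z_ci` and approaches a step function
#' as the responsiveness `v_rt` grows. Any sigmoid between 0 and 1 is
#' admissible on the scaled concentration axis; pass a different function via
#' the `activation_fn` argument of [simulate_guts()] to swap it.
#'
#' @param c_scaled Internal concentration scaled by the reference maximum
#'   `C_i_max` (dimensionless, >= 0).
#' @param z_ci Activation threshold on the scaled concentration axis.
#' @param v_rt Responsiveness (sigmoid slope), > 0.
#' @return Activation level in (0, 1), same length as `c_scaled`.
#' @export
#' @examples
#' activation(c(0, 0.5, 1), z_ci = 0.5, v_rt = 10)
activation <- function(c_scaled, z_ci, v_rt) {
  for (nm in c("c_scaled", "z_ci", "v_rt")) {
    v <- get(nm)
    if (!is.numeric(v) || anyNA(v) || any(!is.finite(v))) {
      abort(paste0("`", nm, "` must be finite and numeric"))
    }
  }
  if (any(c_scaled < 0)) abort("`c_scaled` must be >= 0")
  if (any(v_rt <= 0)) abort("`v_rt` must be > 0")
  stats::plogis(v_rt * (c_scaled - z_ci))
}

#' Stochastic-death hazard rate
#'
#' Piecewise-linear hazard of the GUTS stochastic-death module:
#' \deqn{h = k_k \max(0, D - z) + h_b}
#' where `D` is the damage level (here the *nrf2* fold-change for the RNA
#' variants), `z` the effect threshold, `k_k` the killing rate constant and
#' `h_b` the background hazard.
#'
#' @param damage_level Damage state (fold-change or damage units).
#' @param z Effect threshold (same units as `damage_level`).
#' @param k_k Killing rate constant (damage^-1 h^-1), >= 0.
#' @param h_b Background hazard rate (h^-1), >= 0.
#' @return Hazard rate (h^-1), >= `h_b`.
#' @export
#' @examples
#' hazard_rate(c(0.5, 2, 3), z = 1, k_k = 0.1, h_b = 0.01)
hazard_rate <- function(damage_level, z, k_k, h_b) {
  for (nm in c("damage_level", "z", "k_k", "h_b")) {
    v <- get(nm)
    if (!is.numeric(v) || anyNA(v) || any(!is.finite(v))) {
      abort(paste0("`", nm, "` must be finite and numeric"))
    }
  }
  if (any(k_k < 0)) abort("`k_k` must be >= 0")
  if (any(h_b < 0)) abort("`h_b` must be >= 0")
  k_k * pmax(0, damage_level - z) + h_b
}

#' Survival probability from cumulative hazard
#'
#' Under the stochastic-death assumption the survival probability is
#' \eqn{S = e^{-H}} with `H` the cumulative hazard integrated from exposure
#' start.
#'
#' @param H Cumulative hazard (dimensionless), >= 0.
#' @return Survival probability in (0, 1].
#' @export
#' @examples
#' survival_from_cumulative_hazard(c(0, log(2), 3))
survival_from_cumulative_hazard <- function(H) {
  if (!is.numeric(H) || anyNA(H) || any(!is.finite(H))) {
    abort("`H` must be finite and numeric")
  }
  if (any(H < 0)) abort("`H` must be >= 0")
  exp(-H)
}

#' Scaling context for the RNA variants
#'
#' `C_i_max` is the maximum observed internal concentration over all
#' experiments; internal concentrations are scaled by it inside the
#' activation function to harmonize the scale of `v_rt`. It is a fixed,
#' data-derived constant, not a fitted parameter. `R_0 = 1` makes the modeled
#' RNA quantity identical to the measured fold-change.
#'
#' @param C_i_max Reference maximum internal concentration (umol/L), > 0.
#' @param R_0 Baseline RNA fold-change, > 0 (default 1).
#' @return A list of class `gp_scaling`.
#' @seealso [compute_scaling()] to derive `C_i_max` from an observation table.
#' @export
scaling_context <- function(C_i_max, R_0 = 1) {
  if (!is.numeric(C_i_max) || length(C_i_max) != 1 || !is.finite(C_i_max) ||
      C_i_max <= 0) {
    abort("`C_i_max` must be a single finite value > 0")
  }
  if (!is.numeric(R_0) || length(R_0) != 1 || !is.finite(R_0) || R_0 <= 0) {
    abort("`R_0` must be a single finite value > 0")
  }
  structure(list(C_i_max = C_i_max, R_0 = R_0), class = "gp_scaling")
}

#' Time-derivatives of the GUTS-RNA-pulse state
#'
#' Evaluates the right-hand side of the GUTS-RNA-pulse ODE system at one
#' state:
#' \deqn{dC_i/dt = k_i C_e - k_m P^* C_i}
#' \deqn{dR/dt = r_{rt} A(C_i / C_{i,max}) - k_{rd} \max(0, R - R_0)}
#' \deqn{dP^*/dt = k_p (R - P^*)}
#' \deqn{dH/dt = k_k \max(0, R - z) + h_b}
#' There is no passive elimination pathway: removal of the chemical happens
#' only through the protein-mediated metabolization term. RNA decay acts only
#' above the baseline `R_0` (one-sided first-order decay), which keeps
#' `R >= R_0` for trajectories started at baseline.
#'
#' @param state Named numeric vector with `C_i`, `R`, `P_star`, `H`.
#' @param t Time (h post exposure); the autonomous system ignores it.
#' @param params Named parameter vector for `guts_rna_pulse`
#'   (see [param_registry()]).
#' @param scaling A [scaling_context()].
#' @param C_e External concentration (umol/L), >= 0.
#' @param activation_fn Optional replacement sigmoid
#'   `function(c_scaled, z_ci, v_rt)`.
#' @return Named vector of derivatives `(C_i, R, P_star, H)`.
#' @export
rhs_rna_pulse <- function(state, t = 0, params, scaling, C_e,
                          activation_fn = NULL) {
  p <- validate_params("guts_rna_pulse", params)
  if (!inherits(scaling, "gp_scaling")) abort("`scaling` must be a scaling_context()")
  if (!is.numeric(C_e) || length(C_e) != 1 || !is.finite(C_e) || C_e < 0) {
    abort("`C_e` must be a single finite value >= 0")
  }
  C_i <- state[["C_i"]]; R <- state[["R"]]; P <- state[["P_star"]]
  if (any(!is.finite(c(C_i, R, P)))) abort("non-finite state")
  act_fn <- activation_fn %||% activation
  act <- act_fn(C_i / scaling$C_i_max, p[["z_ci"]], p[["v_rt"]])
  c(
    C_i    = p[["k_i"]] * C_e - p[["k_m"]] * P * C_i,
    R      = p[["r_rt"]] * act - p[["k_rd"]] * max(0, R - scaling$R_0),
    P_star = p[["k_p"]] * (R - P),
    H      = hazard_rate(R, p[["z"]], p[["k_k"]], p[["h_b"]])
  )
}

#' Time-derivatives for any model variant
#'
#' Dispatches on the variant identifier. State layouts: `guts_reduced` uses
#' `(D, H)`; `guts_scaled_damage` and `guts_rna` use `(C_i, D, H)`;
#' `guts_rna_pulse` uses `(C_i, R, P_star, H)`. For `guts_rna` the damage
#' state `D` is the *nrf2* fold-change with baseline `D_0 = R_0`.
#'
#' @inheritParams rhs_rna_pulse
#' @param variant One of [guts_variants()].
#' @return Named vector of state derivatives.
#' @export
rhs_variant <- function(variant, state, t = 0, params, scaling = NULL, C_e) {
  .check_variant(variant)
  if (variant == "guts_rna_pulse") {
    return(rhs_rna_pulse(state, t, params, scaling, C_e))
  }
  p <- validate_params(variant, params)
  if (!is.numeric(C_e) || length(C_e) != 1 || !is.finite(C_e) || C_e < 0) {
    abort("`C_e` must be a single finite value >= 0")
  }
  switch(variant,
    guts_reduced = {
      D <- state[["D"]]
      c(
        D = p[["k_d"]] * (C_e - D),
        H = hazard_rate(D, p[["z"]], p[["k_k"]], p[["h_b"]])
      )
    },
    guts_scaled_damage = {
      C_i <- state[["C_i"]]; D <- state[["D"]]
      c(
        C_i = p[["k_i"]] * C_e - p[["k_e"]] * C_i,
        D   = p[["k_d"]] * (C_i - D),
        H   = hazard_rate(D, p[["z"]], p[["k_k"]], p[["h_b"]])
      )
    },
    guts_rna = {
      D_0 <- if (is.null(scaling)) 1 else scaling$R_0
      C_i <- state[["C_i"]]; D <- state[["D"]]
      c(
        C_i = p[["k_i"]] * C_e - p[["k_e"]] * C_i,
        D   = p[["k_a"]] * C_i - p[["k_r"]] * (D - D_0),
        H   = hazard_rate(D, p[["z"]], p[["k_k"]], p[["h_b"]])
      )
    }
  )
}

# initial state (untreated baseline equilibrium) for a variant
.gp_initial_state <- function(variant, scaling = NULL) {
  R_0 <- if (is.null(scaling)) 1 else scaling$R_0
  switch(variant,
    guts_reduced       = c(D = 0, H = 0),
    guts_scaled_damage = c(C_i = 0, D = 0, H = 0),
    guts_rna           = c(C_i = 0, D = R_0, H = 0),
    guts_rna_pulse     = c(C_i = 0, R = R_0, P_star = R_0, H = 0)
  )
}
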