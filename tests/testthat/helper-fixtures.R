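# shared fixtures: a reference GUTS-RNA-pulse parameter set and scenario
# builders used across the test files

`%||%` <- function(x, y) if (is.null(x)) y else x

gp_test_params <- function(...) {
  p <- c(k_i = 0.2, k_m = 0.05, z_ci = 0.2, v_rt = 20, r_rt = 5,
         k_rd = 1.5, k_p = 0.05, z = 2.5, k_k = 0.05, h_b = 1e-4)
  over <- c(...)
  p[names(over)] <- over
  p
}

gp_test_scaling <- function(C_i_max = 25) scaling_context(C_i_max)

gp_test_scenario <- function(C_e = 5, ...) {
  exposure_scenario("substance_1", C_e = C_e, ...)
}

# literal symbol-by-symbol transcription of the pulse model equations,
# kept independent of the package right-hand side implementation
gp_literal_rhs <- function(state, params, C_i_max, R_0, C_e) {
  with(as.list(c(state, params)), {
    A <- 1 / (1 + exp(-v_rt * (C_i / C_i_max - z_ci)))
    c(
      C_i = k_i * C_e - k_m * P_star * C_i,
      R = r_rt * A - k_rd * max(0, R - R_0),
      P_star = k_p * (R - P_star),
      H = k_k * max(0, R - z) + h_b
    )
  })
}

# brute-force enumeration of the conditional-binomial survival process:
# all monotone survivor-count paths for n organisms over the given survival
# probabilities, with their probabilities
gp_enumerate_paths <- function(n, S) {
  paths <- expand.grid(rep(list(0:n), length(S)))
  keep <- apply(paths, 1, function(x) all(diff(x) <= 0)) & paths[[1]] <= n
  paths <- paths[keep, , drop = FALSE]
  prob <- apply(paths, 1, function(x) {
    exp(as.numeric(conditional_binomial_loglik(as.integer(x), S, n)))
  })
  list(paths = paths, prob = prob)
}
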