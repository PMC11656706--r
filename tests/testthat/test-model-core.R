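test_that("activation sigmoid hits its midpoint, saturates, and rejects bad input", {
  # midpoint: scaled concentration at the threshold gives exactly 1/2
  for (v_rt in c(0.5, 5, 50)) {
    expect_equal(activation(0.5, z_ci = 0.5, v_rt = v_rt), 0.5)
  }
  # direct evaluation of the logistic form
  expect_equal(activation(1.0, z_ci = 0.5, v_rt = 10), 1 / (1 + exp(-5)),
               tolerance = 1e-12)
  expect_equal(activation(1.0, z_ci = 0.5, v_rt = 10), 0.993307,
               tolerance = 1e-6)
  # step-function limit below threshold
  expect_lt(activation(0, z_ci = 0.5, v_rt = 1e4), 1e-300)
  # monotone in concentration, steeper with responsiveness
  cc <- seq(0, 1, length.out = 51)
  expect_true(all(diff(activation(cc, 0.5, 8)) >= 0))
  slope_at_mid <- function(v) {
    (activation(0.5 + 1e-5, 0.5, v) - activation(0.5 - 1e-5, 0.5, v)) / 2e-5
  }
  expect_gt(slope_at_mid(20), slope_at_mid(5))
  expect_true(all(activation(cc, 0.3, 12) > 0 & activation(cc, 0.3, 12) < 1))
  # diagnostics name the offending argument
  expect_error(activation(NaN, 0.5, 10), "c_scaled")
  expect_error(activation(0.5, 0.5, -1), "v_rt")
})

test_that("hazard is piecewise linear with a background floor", {
  expect_equal(hazard_rate(c(0, 0.5, 1), z = 1, k_k = 2, h_b = 0.01),
               rep(0.01, 3))
  expect_equal(hazard_rate(2, z = 1, k_k = 2, h_b = 0.01), 2.01)
  expect_equal(hazard_rate(c(0.1, 7, 100), z = 1, k_k = 0, h_b = 0.3),
               rep(0.3, 3))
  d <- seq(0, 5, by = 0.01)
  h <- hazard_rate(d, z = 2, k_k = 0.4, h_b = 0.05)
  expect_true(all(h >= 0.05))
  expect_true(all(diff(h) >= 0))
})

test_that("survival is the exponential of the negative cumulative hazard", {
  expect_equal(survival_from_cumulative_hazard(0), 1)
  expect_equal(survival_from_cumulative_hazard(log(2)), 0.5)
  expect_error(survival_from_cumulative_hazard(-0.1), ">= 0")
  H <- sort(runif(20, 0, 5))
  expect_true(all(diff(survival_from_cumulative_hazard(H)) <= 0))
})

test_that("pulse-model derivatives match hand evaluations", {
  scaling <- gp_test_scaling(10)
  # unexposed baseline: everything at equilibrium except a tiny activation leak
  p <- gp_test_params(z_ci = 0.5, v_rt = 50, h_b = 0)
  d0 <- rhs_rna_pulse(c(C_i = 0, R = 1, P_star = 1, H = 0),
                      params = p, scaling = scaling, C_e = 0)
  expect_equal(unname(d0[c("C_i", "P_star", "H")]), c(0, 0, 0))
  expect_equal(unname(d0[["R"]]), p[["r_rt"]] * activation(0, 0.5, 50))
  expect_lt(d0[["R"]], 1e-9)
  # metabolization switched off: pure linear uptake
  p2 <- gp_test_params(k_m = 0)
  d2 <- rhs_rna_pulse(c(C_i = 3, R = 2, P_star = 5, H = 0),
                      params = p2, scaling = scaling, C_e = 4)
  expect_equal(unname(d2[["C_i"]]), p2[["k_i"]] * 4)
  # all rates 1, C_i at the reference maximum, logistic activation by hand
  p3 <- c(k_i = 1, k_m = 1, z_ci = 0.5, v_rt = 10, r_rt = 1, k_rd = 1,
          k_p = 1, z = 1, k_k = 1, h_b = 1)
  d3 <- rhs_rna_pulse(c(C_i = 10, R = 2, P_star = 1, H = 0),
                      params = p3, scaling = scaling, C_e = 0)
  expect_equal(unname(d3[["R"]]), 1 / (1 + exp(-5)) - 1 * (2 - 1),
               tolerance = 1e-9)
  expect_equal(unname(d3[["R"]]), -0.006693, tolerance = 1e-4)
  # invalid inputs
  expect_error(rhs_rna_pulse(c(C_i = 0, R = 1, P_star = 1, H = 0),
                             params = p, scaling = scaling, C_e = -1), "C_e")
})

test_that("comparison-variant derivatives satisfy their equilibria", {
  # reduced: damage in equilibrium with the external concentration
  pr <- c(k_d = 0.3, z = 2, k_k = 0.1, h_b = 0)
  d <- rhs_variant("guts_reduced", c(D = 4, H = 0), params = pr, C_e = 4)
  expect_equal(unname(d[["D"]]), 0)
  # scaled damage: absorbing clean state
  ps <- c(k_i = 0.2, k_e = 0.1, k_d = 0.3, z = 2, k_k = 0.1, h_b = 0)
  d <- rhs_variant("guts_scaled_damage", c(C_i = 0, D = 0, H = 0),
                   params = ps, C_e = 0)
  expect_equal(unname(d), c(0, 0, 0))
  # rna: substitution k_a C_i = k_r (D - D_0) nulls the damage derivative
  pn <- c(k_i = 0.2, k_e = 0.1, k_a = 0.4, k_r = 0.4, z = 2, k_k = 0.1, h_b = 0)
  d <- rhs_variant("guts_rna", c(C_i = 1.5, D = 1 + 1.5, H = 0),
                   params = pn, scaling = scaling_context(10), C_e = 0)
  expect_equal(unname(d[["D"]]), 0)
  expect_error(rhs_variant("guts_full", c(D = 0, H = 0), params = pr, C_e = 0),
               "variant")
})

test_that("implementation agrees with a literal transcription of the equations", {
  set.seed(42)
  scaling <- gp_test_scaling(12)
  for (i in 1:100) {
    p <- gp_test_params(
      k_i = runif(1, 0.01, 1), k_m = runif(1, 0, 0.5),
      z_ci = runif(1, 0, 1), v_rt = runif(1, 1, 50),
      r_rt = runif(1, 0.1, 10), k_rd = runif(1, 0.1, 5),
      k_p = runif(1, 0.01, 1), z = runif(1, 0, 5),
      k_k = runif(1, 0, 0.5), h_b = runif(1, 0, 0.05)
    )
    st <- c(C_i = runif(1, 0, 15), R = 1 + runif(1, 0, 5),
            P_star = runif(1, 0, 6), H = runif(1, 0, 3))
    ce <- runif(1, 0, 20)
    got <- rhs_rna_pulse(st, params = p, scaling = scaling, C_e = ce)
    want <- gp_literal_rhs(st, p, C_i_max = 12, R_0 = 1, C_e = ce)
    expect_equal(unname(got), unname(want), tolerance = 1e-12)
  }
})

test_that("transient exposure produces an nrf2 pulse that returns to baseline", {
  # exposure for 12 h, then clean water: C_i rises above the activation
  # threshold and is washed out; R must pulse and relax back to R_0,
  # never dropping below the baseline floor
  profile <- data.frame(time = c(0, 12), C_e = c(8, 0))
  sc <- exposure_scenario("s", C_e = profile, t_end = 96)
  p <- gp_test_params(k_m = 0.4, k_p = 0.3, z_ci = 0.25, v_rt = 30)
  tr <- simulate_guts("guts_rna_pulse", p, gp_test_scaling(10), sc,
                      times = seq(0, 96, by = 0.5))
  expect_gt(max(tr$R), 2)                      # clearly activated
  expect_lt(tail(tr$R, 1), 1.05)               # relaxed back toward baseline
  expect_true(all(tr$R >= 1 - 1e-8))           # floor holds
  # peak R lags the time C_i drops below the activation threshold
  t_peak_R <- tr$time[which.max(tr$R)]
  thr <- p[["z_ci"]] * 10  # threshold on the unscaled axis
  above <- tr$time[tr$C_i > thr]
  expect_gt(t_peak_R, min(above))
})

test_that("parameter validation enforces positivity and completeness", {
  expect_error(validate_params("guts_rna_pulse", gp_test_params()[-1]),
               "missing")
  bad <- gp_test_params(); bad["k_rd"] <- -1
  expect_error(validate_params("guts_rna_pulse", bad), "k_rd")
  # thresholds may sit at zero
  ok <- gp_test_params(z_ci = 0)
  expect_silent(validate_params("guts_rna_pulse", ok))
})

test_that("model configurations round-trip losslessly through YAML", {
  cfg <- list(
    variant = "guts_rna_pulse",
    params = list(substance_1 = gp_test_params(k_i = 1 / 3)),
    error_params = c(sigma_cint = 0.3, sigma_nrf2 = 0.123456789012345),
    sharing = sharing_map("guts_rna_pulse")
  )
  path <- withr::local_tempfile(fileext = ".yaml")
  write_model_config(cfg, path)
  back <- read_model_config(path)
  expect_identical(back$variant, cfg$variant)
  expect_equal(back$params$substance_1, cfg$params$substance_1,
               tolerance = 1e-15)
  expect_equal(back$error_params, cfg$error_params, tolerance = 1e-15)
  expect_identical(back$sharing, cfg$sharing)
})
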