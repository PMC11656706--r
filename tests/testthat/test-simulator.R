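test_that("control treatment stays at baseline with unit survival", {
  sc <- gp_test_scenario(C_e = 0)
  p <- gp_test_params(z_ci = 0.5, v_rt = 200, h_b = 0)
  tr <- simulate_guts("guts_rna_pulse", p, gp_test_scaling(), sc,
                      times = seq(0, 96, by = 4))
  expect_equal(tr$C_i, rep(0, nrow(tr)), tolerance = 1e-8)
  expect_equal(tr$R, rep(1, nrow(tr)), tolerance = 1e-6)
  expect_equal(tr$S, rep(1, nrow(tr)), tolerance = 1e-8)
})

test_that("solver matches closed forms for the degenerate sub-models", {
  # no metabolization: C_i(t) = k_i C_e t (no other elimination pathway)
  sc <- gp_test_scenario(C_e = 3)
  p <- gp_test_params(k_m = 0)
  tt <- c(0, 1.5, 12, 48, 96)
  tr <- simulate_guts("guts_rna_pulse", p, gp_test_scaling(), sc, times = tt)
  expect_equal(tr$C_i[-1], p[["k_i"]] * 3 * tt[-1], tolerance = 1e-6)

  # activation pinned at ~1: saturating RNA response
  # R(t) = R0 + (r_rt / k_rd) (1 - exp(-k_rd t))
  p2 <- gp_test_params(z_ci = 0, v_rt = 1e8, k_m = 0)
  tr2 <- simulate_guts("guts_rna_pulse", p2, gp_test_scaling(), sc, times = tt)
  want <- 1 + (p2[["r_rt"]] / p2[["k_rd"]]) * (1 - exp(-p2[["k_rd"]] * tt))
  expect_equal(tr2$R, want, tolerance = 1e-6)

  # one-compartment damage: D(t) = C_e (1 - exp(-k_d t))
  pr <- c(k_d = 0.08, z = 1e6, k_k = 0.1, h_b = 0)
  tr3 <- simulate_guts("guts_reduced", pr, scenario = sc, times = tt)
  expect_equal(tr3$D, 3 * (1 - exp(-0.08 * tt)), tolerance = 1e-6)

  # sub-threshold damage: exponential survival at the background hazard
  pr2 <- c(k_d = 0.08, z = 1e6, k_k = 0.1, h_b = 0.01)
  tr4 <- simulate_guts("guts_reduced", pr2, scenario = sc, times = tt)
  expect_equal(tr4$S, exp(-0.01 * tt), tolerance = 1e-7)
})

test_that("protein state relaxes exponentially toward a held RNA level", {
  # pin R by switching expression and decay off after initializing R via a
  # strong short pulse is awkward; instead hold R at baseline and displace P*
  # via its own equation: with r_rt = 0 and R = R0 = 1, a trajectory for
  # P* from the model is P*(t) = R + (P0 - R) exp(-k_p t); at baseline
  # P0 = R so instead verify the relaxation rate on the rna variant's
  # tracking structure using the pulse model with frozen RNA (k_rd huge).
  p <- gp_test_params(r_rt = 1e-9, k_rd = 1e3, k_p = 0.2, k_m = 0, h_b = 0)
  sc <- gp_test_scenario(C_e = 0)
  # start from a perturbed protein level by integrating the R-level rhs
  scaling <- gp_test_scaling()
  st <- c(C_i = 0, R = 1, P_star = 4, H = 0)
  rhs <- function(t, y, parms) {
    list(unname(rhs_rna_pulse(setNames(y, names(st)), t, p, scaling, 0)))
  }
  tt <- seq(0, 30, by = 1)
  sol <- deSolve::lsoda(st, tt, rhs, NULL, rtol = 1e-9, atol = 1e-11)
  want <- 1 + (4 - 1) * exp(-0.2 * tt)
  expect_equal(unname(sol[, "P_star"]), want, tolerance = 1e-6)
})

test_that("tolerance refinement leaves the solution unchanged to 1e-6", {
  sc <- gp_test_scenario(C_e = 8)
  p <- gp_test_params(k_m = 0.4)    # metabolization-overshoot regime
  tt <- seq(0, 96, by = 2)
  a <- simulate_guts("guts_rna_pulse", p, gp_test_scaling(), sc, times = tt,
                     rtol = 1e-7, atol = 1e-9)
  b <- simulate_guts("guts_rna_pulse", p, gp_test_scaling(), sc, times = tt,
                     rtol = 1e-8, atol = 1e-10)
  for (v in c("C_i", "R", "P_star", "S")) {
    expect_equal(a[[v]], b[[v]], tolerance = 1e-6)
  }
})

test_that("coarse grids subsample the fine-grid solution", {
  sc <- gp_test_scenario(C_e = 6)
  p <- gp_test_params()
  fine <- simulate_guts("guts_rna_pulse", p, gp_test_scaling(), sc,
                        times = seq(0, 96, by = 1))
  coarse <- simulate_guts("guts_rna_pulse", p, gp_test_scaling(), sc,
                          times = c(0, 12, 24, 48, 96))
  sub <- fine[fine$time %in% coarse$time, ]
  for (v in c("C_i", "R", "P_star", "H", "S")) {
    expect_equal(coarse[[v]], sub[[v]], tolerance = 1e-6)
  }
})

test_that("piecewise-constant exposure is honored segment by segment", {
  profile <- data.frame(time = c(0, 24), C_e = c(4, 0))
  sc <- exposure_scenario("s", C_e = profile, t_end = 96)
  p <- gp_test_params(k_m = 0)
  tr <- simulate_guts("guts_rna_pulse", p, gp_test_scaling(), sc,
                      times = c(0, 12, 24, 48, 96))
  # linear uptake during exposure, frozen afterwards (no elimination path)
  expect_equal(tr$C_i[tr$time == 24], p[["k_i"]] * 4 * 24, tolerance = 1e-6)
  expect_equal(tr$C_i[tr$time == 96], p[["k_i"]] * 4 * 24, tolerance = 1e-6)
})

test_that("batch simulation is order-preserving and names missing substances", {
  sc1 <- exposure_scenario("a", 2); sc2 <- exposure_scenario("b", 5)
  params <- list(a = gp_test_params(), b = gp_test_params(k_i = 0.4))
  scaling <- gp_test_scaling()
  tt <- c(0, 24, 96)
  one <- simulate_guts("guts_rna_pulse", params$a, scaling, sc1, times = tt)
  batch <- batch_simulate("guts_rna_pulse", params, scaling, list(sc1, sc2),
                          times = tt)
  expect_length(batch, 2)
  expect_equal(batch[[1]]$C_i, one$C_i)
  perm <- batch_simulate("guts_rna_pulse", params, scaling, list(sc2, sc1),
                         times = tt)
  expect_equal(perm[[2]]$C_i, batch[[1]]$C_i)
  expect_error(
    batch_simulate("guts_rna_pulse", params["a"], scaling, list(sc2), times = tt),
    "'b'"
  )
})

test_that("a custom activation sigmoid can replace the logistic", {
  sc <- gp_test_scenario(C_e = 6)
  p <- gp_test_params()
  probit <- function(c_scaled, z_ci, v_rt) pnorm(v_rt * (c_scaled - z_ci))
  tr_probit <- simulate_guts("guts_rna_pulse", p, gp_test_scaling(), sc,
                             times = c(0, 24, 96), activation_fn = probit)
  tr_logit <- simulate_guts("guts_rna_pulse", p, gp_test_scaling(), sc,
                            times = c(0, 24, 96))
  expect_false(isTRUE(all.equal(tr_probit$R, tr_logit$R, tolerance = 1e-4)))
  # and the R-level path with the default sigmoid reproduces the C path
  tr_r <- simulate_guts("guts_rna_pulse", p, gp_test_scaling(), sc,
                        times = c(0, 24, 96), activation_fn = activation)
  expect_equal(tr_r$R, tr_logit$R, tolerance = 1e-6)
})

test_that("scaling is the maximum observed internal concentration with unit R0", {
  obs <- tibble::tibble(
    treatment_id = "t1", substance = "s", endpoint = c("cint", "cint", "cint", "nrf2"),
    time = c(1, 2, 3, 3), value = c(2.0, 5.5, 1.1, 9), n_at_risk = NA_integer_
  )
  sc <- compute_scaling(obs)
  expect_equal(sc$C_i_max, 5.5)
  expect_equal(sc$R_0, 1)
  expect_equal(compute_scaling(obs[2, ])$C_i_max, 5.5)
  expect_error(compute_scaling(obs[4, ]), "concentration")
})

test_that("the study-scale scenario batch solves under default tolerances", {
  b_design <- generate_design(design_config("paper_scale"), seed = 3)
  scen <- scenarios_from_design(b_design)
  expect_length(scen, 202)
  truth <- default_ground_truth(b_design$config$substances)
  trs <- batch_simulate("guts_rna_pulse", truth$params,
                        gp_test_scaling(20), scen, times = c(0, 24, 48, 96))
  expect_length(trs, 202)
  ok <- vapply(trs, function(tr) all(is.finite(tr$S)) && all(diff(tr$S) <= 1e-12),
               logical(1))
  expect_true(all(ok))
})
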