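test_that("unit-interval initialization maps onto the prior's log scale", {
  pr <- default_priors("guts_rna_pulse")
  # center maps to the prior medians exactly
  expect_equal(unname(init_from_unit_interval(rep(0, nrow(pr)), pr)),
               pr$median, tolerance = 1e-12)
  # u = 1 with log-sd 2 is median * e^2
  u <- rep(0, nrow(pr)); u[1] <- 1
  expect_equal(init_from_unit_interval(u, pr)[[1]], pr$median[1] * exp(2))
  # symmetric about the median on the log scale
  up <- init_from_unit_interval(rep(1, nrow(pr)), pr)
  dn <- init_from_unit_interval(rep(-1, nrow(pr)), pr)
  expect_equal(log(up) - log(pr$median), -(log(dn) - log(pr$median)),
               tolerance = 1e-12)
  expect_error(init_from_unit_interval(rep(1.5, nrow(pr)), pr), "\\[-1, 1\\]")
})

test_that("the initializer is a bounded start generator, not a prior sampler", {
  # push-forward of u ~ U(-1,1) must differ from the log-normal prior:
  # it is bounded to +/- 1 prior log-sd, the prior is not
  pr <- default_priors("guts_reduced")[1, ]
  set.seed(1)
  u_draws <- vapply(runif(4000, -1, 1),
                    function(u) init_from_unit_interval(u, pr)[[1]],
                    numeric(1))
  ks <- suppressWarnings(
    stats::ks.test(log(u_draws), "pnorm", pr$logmedian, pr$logsd)
  )
  expect_gt(ks$statistic, 0.1)
  expect_lt(ks$p.value, 1e-6)
  expect_true(all(abs(log(u_draws) - pr$logmedian) <= pr$logsd + 1e-12))
})

test_that("both engines recover a known conjugate posterior on a toy problem", {
  # normal-normal model on the log scale: prior N(0, 1), 10 observations of
  # a log-parameter with known sd 0.5 -> closed-form posterior
  y <- c(0.3, 0.5, 0.1, 0.45, 0.2, 0.6, 0.35, 0.15, 0.4, 0.5)
  sd_y <- 0.5
  post_var <- 1 / (1 / 1 + length(y) / sd_y^2)
  post_mean <- post_var * sum(y) / sd_y^2
  logpost <- function(theta) {
    structure(
      dnorm(theta, 0, 1, log = TRUE) +
        sum(dnorm(y, theta, sd_y, log = TRUE)),
      loglik = 0
    )
  }
  set.seed(7)
  mc <- gutspulse:::.gp_mcmc(logpost, c(x = -1), warmup = 500, draws = 4000)
  mc_mean <- mean(mc$draws)
  mcse <- sd(mc$draws) / sqrt(100)  # conservative ESS of 100
  expect_lt(abs(mc_mean - post_mean), 3 * mcse + 0.02)
  sv <- gutspulse:::.gp_svi(logpost, c(x = -1), draws = 4000)
  expect_equal(mean(sv$draws), post_mean, tolerance = 0.05)
  expect_equal(sd(sv$draws), sqrt(post_var), tolerance = 0.25)
  # engine-agnostic contract: the two posteriors agree
  expect_equal(mean(sv$draws), mc_mean, tolerance = 0.1)
})

test_that("multistart fitting records per-start losses and is seed-reproducible", {
  b <- make_benchmark("toy", seed = 31)
  sv <- dplyr::filter(b$observations, endpoint == "survival")
  scen <- scenarios_from_design(b$design)
  fit <- multistart_fit("guts_reduced", sv, scen,
                        n_starts = 3, seed = 17, engine = "mcmc",
                        draws = 150, warmup = 100)
  expect_s3_class(fit, "gp_fit")
  expect_identical(nrow(fit$starts), 3L)
  expect_identical(fit$best_start, which.min(fit$starts$loss))
  expect_identical(nrow(fit$draws), 150L)
  expect_identical(fit$k, 4L)  # guts_reduced has no error parameters
  # bitwise-reproducible recorded summaries
  fit2 <- multistart_fit("guts_reduced", sv, scen,
                         n_starts = 3, seed = 17, engine = "mcmc",
                         draws = 150, warmup = 100)
  expect_identical(fit$starts$loss, fit2$starts$loss)
  expect_identical(fit$loglik_max, fit2$loglik_max)
  expect_identical(fit$draws, fit2$draws)
  # a single start equals the first start of the seeded stream
  fit1 <- multistart_fit("guts_reduced", sv, scen,
                         n_starts = 1, seed = 17, engine = "mcmc",
                         draws = 150, warmup = 100)
  expect_identical(nrow(fit1$starts), 1L)
  # tidy/glance surfaces
  td <- tidy(fit)
  expect_identical(td$term, fit$fpt$name)
  expect_true(all(td$conf.low <= td$estimate & td$estimate <= td$conf.high))
  gl <- glance(fit)
  expect_identical(gl$k, 4L)
  expect_equal(gl$bic, bic(fit$loglik_max, 4, nrow(sv)))
})

test_that("credible-interval envelopes behave like nested quantiles", {
  b <- make_benchmark("toy", seed = 33)
  sv <- dplyr::filter(b$observations, endpoint == "survival")
  scen <- scenarios_from_design(b$design)
  fit <- multistart_fit("guts_reduced", sv, scen,
                        n_starts = 2, seed = 3, engine = "mcmc",
                        draws = 80, warmup = 80)
  sc <- scen[[which(b$design$treatments$C_e > 0)[1]]]
  tt <- seq(0, 96, by = 8)
  env95 <- posterior_trajectory_bci(fit, sc, level = 0.95, times = tt)
  env50 <- posterior_trajectory_bci(fit, sc, level = 0.5, times = tt)
  env100 <- posterior_trajectory_bci(fit, sc, level = 1, times = tt)
  expect_true(all(env95$lower <= env95$median + 1e-12 &
                    env95$median <= env95$upper + 1e-12))
  # nesting: wider level, wider band
  expect_true(all(env95$lower <= env50$lower + 1e-12))
  expect_true(all(env95$upper >= env50$upper - 1e-12))
  expect_true(all(env100$lower <= env95$lower + 1e-12))
  # a single-draw posterior collapses the band
  fit1 <- fit
  fit1$draws <- fit$draws[1, ]
  env1 <- posterior_trajectory_bci(fit1, sc, times = tt)
  expect_equal(env1$lower, env1$upper)
  expect_equal(env1$lower, env1$median)
})

test_that("cluster detection separates constructed modes and respects labels", {
  set.seed(5)
  # two Gaussians 10 sd apart in 2-d log-parameter space
  a <- matrix(rnorm(60, 0, 0.1), ncol = 2)
  bm <- matrix(rnorm(60, 0, 0.1), ncol = 2); bm[, 1] <- bm[, 1] + 1
  m <- rbind(a, bm)
  colnames(m) <- c("k_k", "r_rt")
  losses <- c(rep(1, 30), rep(2, 30))
  res <- detect_posterior_clusters(m, losses = losses)
  expect_identical(nrow(res$clusters), 2L)
  expect_identical(length(unique(res$labels[1:30])), 1L)
  expect_identical(length(unique(res$labels[31:60])), 1L)
  expect_false(res$labels[1] == res$labels[31])
  # label partition is invariant to permuting the starts
  perm <- sample(nrow(m))
  res_p <- detect_posterior_clusters(m[perm, ], losses = losses[perm])
  same <- outer(res$labels[perm], res$labels[perm], "==")
  same_p <- outer(res_p$labels, res_p$labels, "==")
  expect_identical(same, same_p)
  # all identical end points: one cluster
  one <- detect_posterior_clusters(matrix(1, 12, 2))
  expect_identical(nrow(one$clusters), 1L)
  # single start is a valid degenerate input
  single <- detect_posterior_clusters(matrix(c(0.3, 0.4), 1, 2))
  expect_identical(single$labels, 1L)
})

test_that("model comparison sorts by BIC and refuses mismatched data", {
  b <- make_benchmark("toy", seed = 41)
  sv <- dplyr::filter(b$observations, endpoint == "survival")
  scen <- scenarios_from_design(b$design)
  f_red <- multistart_fit("guts_reduced", sv, scen, n_starts = 2, seed = 5,
                          engine = "mcmc", draws = 100, warmup = 100)
  f_red2 <- multistart_fit("guts_reduced", sv, scen, n_starts = 2, seed = 6,
                           engine = "mcmc", draws = 100, warmup = 100)
  cmp <- compare_models(a = f_red, b = f_red2)
  expect_identical(cmp$delta_bic[1], 0)
  expect_true(all(diff(cmp$bic) >= 0))
  expect_equal(cmp$delta_bic[2], abs(f_red$bic - f_red2$bic))
  # single fit: delta is zero
  expect_identical(compare_models(f_red)$delta_bic, 0)
  # order invariance of the ranking
  cmp_r <- compare_models(b = f_red2, a = f_red)
  expect_identical(cmp$model, cmp_r$model)
  # different observation tables are rejected
  b2 <- make_benchmark("toy", seed = 42)
  sv2 <- dplyr::filter(b2$observations, endpoint == "survival")
  f_other <- multistart_fit("guts_reduced", sv2,
                            scenarios_from_design(b2$design),
                            n_starts = 1, seed = 5, engine = "mcmc",
                            draws = 50, warmup = 50)
  expect_error(compare_models(f_red, f_other), "different observation tables")
})

test_that("the variational engine also drives a model fit end to end", {
  b <- make_benchmark("toy", seed = 51)
  sv <- dplyr::filter(b$observations, endpoint == "survival")
  scen <- scenarios_from_design(b$design)
  fit <- multistart_fit("guts_reduced", sv, scen, n_starts = 1, seed = 2,
                        engine = "variational", draws = 200)
  expect_s3_class(fit, "gp_fit")
  expect_true(is.finite(fit$bic))
  expect_identical(nrow(fit$draws), 200L)
})
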