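test_that("estimator names parse to the right model subsets", {
  sp <- parse_estimator("MR000010", 3, 3)
  expect_equal(sp$type, "mr")
  expect_equal(sp$ps, integer(0))
  expect_equal(sp$or, 2L)
  sp2 <- parse_estimator("MR111111", 3, 3)
  expect_equal(sp2$ps, 1:3)
  expect_equal(sp2$or, 1:3)
  sp3 <- parse_estimator("MR101", 2, 1)
  expect_equal(sp3$ps, 1L)
  expect_equal(sp3$or, 1L)
  expect_equal(parse_estimator("IPW.model2", 3, 3)$ps, 2L)
  expect_equal(parse_estimator("OR.model3", 3, 3)$or, 3L)
  expect_error(parse_estimator("MR0000", 3, 3), "6 candidate")
  expect_error(parse_estimator("IPW.model4", 3, 3))
  expect_error(parse_estimator("TMLE", 3, 3), "unrecognised")
})

test_that("Hajek IPW matches hand-computed arithmetic", {
  z <- c(1, 1, 0, 0); y <- c(2, 4, 1, 3); p <- c(0.5, 0.25, 0.5, 0.25)
  expect_equal(ipw_point(z, y, p), 10 / 3 - 1.8)
  # constant propensity: weights cancel, both forms give the mean difference
  expect_equal(ipw_point(z, y, rep(0.5, 4)), 3 - 2)
  expect_equal(ipw_point(z, y, rep(0.5, 4), normalize = FALSE), 3 - 2)
  expect_error(ipw_point(c(1, 1), c(1, 2), c(0.5, 0.5)), "empty")
})

test_that("g-computation averages the counterfactual contrast", {
  expect_equal(or_point(rep(2, 5), rep(2, 5)), 0)
  expect_equal(or_point(1:5 + 1, 1:5), 1)
})

test_that("MR with no models reduces exactly to the difference of arm means", {
  d <- tiny_data(150, seed = 14)
  sc <- mr_scenario("T1")
  fit <- mr_ate(d, sc$ps_models, sc$or_models, estimators = "MR000000")
  naive <- mean(d$Y[d$Z == 1]) - mean(d$Y[d$Z == 0])
  expect_equal(unname(coef(fit)), naive, tolerance = 1e-12)
  # lazy fitting: no candidate model should have been trained
  expect_false(any(fit$candidates$ps_fitted))
  expect_false(any(fit$candidates$or_fitted))
})

test_that("a constant candidate model never changes the MR estimate", {
  d <- tiny_data(200, seed = 15)
  fit0 <- mr_ate(d, ps_models = list(ps_glm(~ X1 + X2)),
                 or_models = list(or_lm(~ X1)), estimators = "MR11")
  fit1 <- mr_ate(d, ps_models = list(ps_glm(~ X1 + X2), ps_glm(~ 1)),
                 or_models = list(or_lm(~ X1)), estimators = "MR111")
  expect_equal(unname(coef(fit1)), unname(coef(fit0)), tolerance = 1e-10)
})

test_that("MR calibration transfers to the weighted candidate means", {
  d <- sim_ate_data(500, seed = 16)
  fc <- fit_candidates(d, ps_models = list(ps_glm(true_ps_formula)),
                       or_models = list(or_lm(true_or_formula)))
  res <- mr_point(fc, d$Z, d$Y, ps = 1L, or = 1L)
  w1 <- res$el_treated$weights
  w0 <- res$el_control$weights
  expect_lt(abs(sum(w1 * fc$ps_hat[d$Z == 1, 1]) - fc$theta1[1]), 1e-6)
  expect_lt(abs(sum(w1 * fc$m1_hat[d$Z == 1, 1]) - fc$eta1[1]), 1e-6)
  expect_lt(abs(sum(w0 * (1 - fc$ps_hat[d$Z == 0, 1])) - fc$theta0[1]), 1e-6)
  expect_lt(abs(sum(w0 * fc$m0_hat[d$Z == 0, 1]) - fc$eta0[1]), 1e-6)
  expect_true(is.finite(res$estimate))
})

test_that("MR estimators with a correct OR model are unbiased", {
  # scaled-down double-robustness check: 200 replications at n = 2000 with
  # the generator's own outcome terms in the OR candidate
  reps <- 200
  est <- matrix(NA_real_, reps, 2)
  for (r in 1:reps) {
    d <- sim_ate_data(2000, seed = 60000 + r)
    fit <- mr_ate(d, ps_models = list(ps_glm(true_ps_formula)),
                  or_models = list(or_lm(true_or_formula)),
                  estimators = c("MR01", "MR11"))
    est[r, ] <- coef(fit)
  }
  for (j in 1:2) {
    bias <- 100 * mean(est[, j] - 1)
    expect_lt(abs(bias), 1 + 3 * mc_se_bias_pct(est[, j]))
  }
})

test_that("mr_ate returns a well-formed model object", {
  d <- tiny_data(200, seed = 17)
  fit <- mr_ate(d, ps_models = list(ps_glm(~ X1 + X2)),
                or_models = list(or_lm(~ X1)),
                estimators = c("MR11", "IPW.model1", "OR.model1"),
                B = 25, seed = 2)
  expect_s3_class(fit, "mr_ate")
  expect_named(coef(fit), c("MR11", "IPW.model1", "OR.model1"))
  ci <- confint(fit)
  expect_equal(dim(ci), c(3L, 2L))
  expect_true(all(ci[, 1] <= coef(fit) & coef(fit) <= ci[, 2]))
  expect_output(print(fit), "Multiply robust")
  expect_output(print(summary(fit)), "Candidate models fitted")
})
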