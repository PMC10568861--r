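test_that("an all-zero constraint matrix yields exact uniform weights", {
  G <- matrix(0, 7, 3)
  sol <- el_solve(G)
  expect_true(sol$converged)
  expect_identical(sol$iterations, 0L)
  expect_equal(sol$rho, rep(0, 3))
  expect_equal(sol$weights, rep(1 / 7, 7))
})

test_that("Newton matches the 1-D bisection oracle on random instances", {
  set.seed(500)
  tried <- 0
  while (tried < 100) {
    m <- sample(3:10, 1)
    g <- rnorm(m, sd = runif(1, 0.1, 1))
    g <- g - mean(g) * runif(1, 0, 1.5)  # vary how centred the column is
    if (!(any(g > 0) && any(g < 0))) next
    # keep the root strictly inside the solver's feasibility buffer
    root <- tryCatch(el_bisect_1d(g), error = function(e) NULL)
    if (is.null(root) || any(1 + root * g < 2 / m^2)) next
    tried <- tried + 1
    sol <- el_solve(matrix(g, ncol = 1), tol = 1e-11)
    expect_true(sol$converged)
    expect_lt(abs(sol$rho - root), 1e-8 * (1 + abs(root)))
  }
})

test_that("the dual objective is monotone non-increasing over iterates", {
  set.seed(501)
  for (i in 1:20) {
    G <- matrix(rnorm(60 * 3, sd = 0.3), 60, 3)
    G <- sweep(G, 2, colMeans(G) * runif(1))  # roughly centred constraints
    sol <- el_solve(G)
    expect_true(all(diff(sol$f_path) <= 1e-10))
  }
})

test_that("duplicated constraint columns are dropped and harmless", {
  g <- c(-0.3, 0.1, 0.2, -0.05, 0.15)
  sol1 <- el_solve(matrix(g, ncol = 1))
  sol2 <- el_solve(cbind(g, g))
  expect_true(sol2$converged)
  expect_equal(sol2$dropped, 2L)
  expect_equal(sol2$weights, sol1$weights, tolerance = 1e-10)
  expect_equal(sol2$rho[2], 0)
})

test_that("EL weights satisfy every calibration constraint on real fits", {
  d <- sim_ate_data(600, seed = 55)
  fc <- fit_candidates(d,
    ps_models = list(ps_glm(true_ps_formula), ps_glm(~ I(X1^2) + I(X2^2))),
    or_models = list(or_lm(~ X1 + X2 + X3 + X8 + X9 + X10 + I(X1^2) + I(X2^2))))
  for (arm in c("treated", "control")) {
    G <- el_constraints(fc, d$Z, arm)
    sol <- el_weights(G)
    w <- sol$weights
    expect_true(all(w > 0))
    expect_lt(abs(sum(w) - 1), 1e-8)
    idx <- if (arm == "treated") d$Z == 1 else d$Z == 0
    if (arm == "treated") {
      expect_lt(max(abs(colSums(w * fc$ps_hat[idx, ]) - fc$theta1)), 1e-6)
      expect_lt(abs(sum(w * fc$m1_hat[idx, 1]) - fc$eta1[1]), 1e-6)
    } else {
      expect_lt(max(abs(colSums(w * (1 - fc$ps_hat[idx, ])) - fc$theta0)),
                1e-6)
      expect_lt(abs(sum(w * fc$m0_hat[idx, 1]) - fc$eta0[1]), 1e-6)
    }
    # positivity condition on the Lagrange multipliers
    expect_true(all(1 + drop(G %*% sol$rho[seq_len(ncol(G))]) > 0))
  }
})

test_that("constraint rows reconstruct the centred model values", {
  d <- tiny_data(120, seed = 9)
  fc <- fit_candidates(d, ps_models = list(ps_glm(~ X1 + X3)),
                       or_models = list(or_lm(~ X1 + X2)))
  G1 <- el_constraints(fc, d$Z, "treated")
  idx1 <- d$Z == 1
  expect_equal(unname(G1[, 1]), unname(fc$ps_hat[idx1, 1] - fc$theta1[1]))
  expect_equal(unname(G1[, 2]), unname(fc$m1_hat[idx1, 1] - fc$eta1[1]))
  G0 <- el_constraints(fc, d$Z, "control")
  idx0 <- d$Z == 0
  expect_equal(unname(G0[, 1]),
               unname((1 - fc$ps_hat[idx0, 1]) - fc$theta0[1]))
  # a constant PS model centres to an all-zero column
  fc2 <- fit_candidates(d, ps_models = list(ps_glm(~ 1)))
  expect_lt(max(abs(el_constraints(fc2, d$Z, "treated"))), 1e-12)
})

test_that("infeasible calibration targets raise a convex-hull error", {
  G <- matrix(abs(rnorm(20)) + 0.1, ncol = 1)  # all positive: no root
  sol <- el_solve(G)
  expect_false(sol$converged)
  expect_error(el_weights(G), class = "mrate_convex_hull_error")
})

test_that("EL weights maximise the empirical likelihood on a 3-point problem", {
  g <- c(-0.3, 0.1, 0.2)
  sol <- el_weights(matrix(g, ncol = 1))
  # all feasible weight vectors form a 1-parameter family:
  # w = w_el + t * v with v spanning the null space of rbind(1, g)
  v <- c(g[2] - g[3], g[3] - g[1], g[1] - g[2])
  ts <- seq(-1, 1, length.out = 100001)
  best <- max(vapply(ts, function(t) {
    w <- sol$weights + t * v
    if (any(w <= 0)) return(-Inf)
    prod(w)
  }, numeric(1)))
  expect_lte(best, prod(sol$weights) * (1 + 1e-8))
})
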