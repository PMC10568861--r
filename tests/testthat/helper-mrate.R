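# One-dimensional empirical-likelihood oracle: solves
# sum_i g_i / (1 + rho * g_i) = 0 by bisection on the feasible interval
# {rho : 1 + rho * g_i > 0 for all i}.  Requires g to contain both signs
# (otherwise no root exists).
el_bisect_1d <- function(g, tol = 1e-13) {
  stopifnot(any(g > 0), any(g < 0))
  lo <- -1 / max(g) + 1e-12
  hi <- -1 / min(g) - 1e-12
  score <- function(rho) sum(g / (1 + rho * g))
  stopifnot(score(lo) * score(hi) < 0)
  stats::uniroot(score, c(lo, hi), tol = tol)$root
}

# Monte-Carlo standard errors of the aggregate metrics, estimated from the
# replication spread (delta method for the RMSE).
mc_se_bias_pct <- function(est) 100 * stats::sd(est) / sqrt(length(est))
mc_se_rmse <- function(est, true = 1) {
  e2 <- (est - true)^2
  stats::sd(e2) / (2 * sqrt(mean(e2)) * sqrt(length(e2)))
}

# Small deterministic dataset with a guaranteed mix of both arms.
tiny_data <- function(n = 40, seed = 123) sim_ate_data(n, seed = seed)

# Correctly specified candidate formulas for the built-in generator
# (the OR formula carries every outcome term, including X4).
true_ps_formula <- ~ X1 + X2 + X3 + X4 + X5 + X6 + X7
true_or_formula <- ~ X1 + X2 + X3 + X4 + X8 + X9 + X10 + I(X1^2) + I(X2^2)
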