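#' Built-in Monte-Carlo scenarios
#'
#' Four candidate-model configurations evaluated against the synthetic
#' data-generating process of [sim_ate_data()].  Each supplies three PS
#' models (a 4-unit network, then two logistic regressions) and three OR
#' models (a 4-unit network, then two linear regressions), so MR estimator
#' names carry six digits mapping left-to-right to
#' `pi1, pi2, pi3, m1, m2, m3`:
#'
#' * `"T1"`: the second PS model (`X1..X7`) and second OR model
#'   (`X1, X2, X3, X8, X9, X10, X1^2, X2^2`) match the generating equations;
#'   networks see the true covariate sets.
#' * `"T2"`: every parametric model misspecified (`pi2` reduced to
#'   `X1, X2, X5`; `m2` to `X1, X2, X10`); networks on true covariates.
#' * `"T3"` / `"T4"`: as T1 / T2 but the networks receive all ten covariates.
#'
#' The third PS model (squared covariates) and third OR model (pairwise
#' interactions) are misspecified in every scenario.
#'
#' @param id One of `"T1"`, `"T2"`, `"T3"`, `"T4"`.
#' @return A list with `id`, `ps_models`, `or_models`.
#' @examples
#' sc <- mr_scenario("T1")
#' length(sc$ps_models)
#' @export
mr_scenario <- function(id = c("T1", "T2", "T3", "T4")) {
  id <- match.arg(id)
  all_x <- ~ X1 + X2 + X3 + X4 + X5 + X6 + X7 + X8 + X9 + X10
  nn_ps_f <- if (id %in% c("T1", "T2")) {
    ~ X1 + X2 + X3 + X4 + X5 + X6 + X7
  } else all_x
  nn_or_f <- if (id %in% c("T1", "T2")) {
    ~ X1 + X2 + X3 + X4 + X8 + X9 + X10
  } else all_x
  ps2_f <- if (id %in% c("T1", "T3")) {
    ~ X1 + X2 + X3 + X4 + X5 + X6 + X7
  } else {
    ~ X1 + X2 + X5
  }
  or2_f <- if (id %in% c("T1", "T3")) {
    ~ X1 + X2 + X3 + X8 + X9 + X10 + I(X1^2) + I(X2^2)
  } else {
    ~ X1 + X2 + X10
  }
  list(
    id = id,
    ps_models = list(
      ps_nnet(nn_ps_f),
      ps_glm(ps2_f),
      ps_glm(~ I(X1^2) + I(X2^2) + I(X3^2) + I(X4^2) + I(X5^2) +
               I(X6^2) + I(X7^2))
    ),
    or_models = list(
      or_nnet(nn_or_f),
      or_lm(or2_f),
      or_lm(~ X1:X2 + X3:X4 + X8:X9 + X1:X8 + X2:X9 + X3:X10)
    )
  )
}

#' Run a single simulation replication
#'
#' Draws one dataset of size `n` from the synthetic design with a
#' replication-specific seed, fits the scenario's candidate models once, and
#' evaluates every requested estimator (with a bootstrap interval when
#' `B > 0`).
#'
#' @param scenario A list from [mr_scenario()] (or any list with
#'   `ps_models` / `or_models`).
#' @param n Sample size.
#' @param estimators Character vector of estimator names.
#' @param seed Replication seed.
#' @param B Bootstrap resamples per replication (0 = point estimates only).
#' @return The `estimates` data frame of [mr_ate()], with the estimate set
#'   to `NA` for estimators that failed in this replication.
#' @export
run_replication <- function(scenario, n, estimators, seed, B = 0L) {
  d <- sim_ate_data(n, seed = seed)
  fit <- tryCatch(
    mr_ate(d, ps_models = scenario$ps_models, or_models = scenario$or_models,
           estimators = estimators, B = B, seed = seed),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    data.frame(estimator = estimators, estimate = NA_real_, se = NA_real_,
               ci_lower = NA_real_, ci_upper = NA_real_,
               boot_failed = NA_integer_, stringsAsFactors = FALSE)
  } else {
    fit$estimates
  }
}

#' Aggregate replication estimates into performance metrics
#'
#' @param estimates Vector of replication point estimates (`NA` = failed).
#' @param ci_lower,ci_upper Optional per-replication 95% interval bounds.
#' @param true_ate True effect (1 in the built-in design).
#' @return One-row data frame: `bias_pct` (signed mean relative bias, %),
#'   `rmse`, `coverage_pct` (`NA` without intervals), `n_converged`.
#' @examples
#' compute_metrics(c(1.1, 0.9))  # bias 0%, RMSE 0.1
#' @export
compute_metrics <- function(estimates, ci_lower = NULL, ci_upper = NULL,
                            true_ate = 1) {
  ok <- !is.na(estimates)
  if (!any(ok)) stop("all replications failed; no metrics to compute")
  est <- estimates[ok]
  bias_pct <- 100 * mean((est - true_ate) / true_ate)
  rmse <- sqrt(mean((est - true_ate)^2))
  coverage_pct <- NA_real_
  if (!is.null(ci_lower) && !all(is.na(ci_lower[ok]))) {
    covered <- ci_lower[ok] <= true_ate & true_ate <= ci_upper[ok]
    coverage_pct <- 100 * mean(covered)
  }
  data.frame(bias_pct = bias_pct, rmse = rmse, coverage_pct = coverage_pct,
             n_converged = sum(ok))
}

#' Run a Monte-Carlo scenario
#'
#' Replicates the synthetic design `n_reps` times and aggregates each
#' estimator's mean relative bias (%), RMSE and (when `B > 0`) 95% interval
#' coverage.  Replication seeds are pre-drawn from `base_seed`, so results
#' are identical for any `workers` count, and failed replications
#' (convex-hull violations, degenerate resamples) are dropped from the
#' metrics and reported in `n_converged`.
#'
#' @inheritParams run_replication
#' @param n_reps Number of replications.
#' @param base_seed Master seed.
#' @param workers Parallel workers (forked; `1` = serial).
#' @return An object of class `mr_sim`: list with `summary` (one row per
#'   estimator), the `estimates` matrix (`n_reps x k`), interval arrays, and
#'   the run configuration.
#' @examples
#' sc <- mr_scenario("T1")
#' sim <- run_scenario(sc, n = 200, n_reps = 3,
#'                     estimators = c("IPW.model2", "OR.model2"),
#'                     base_seed = 1)
#' sim$summary
#' @export
run_scenario <- function(scenario, n, n_reps, estimators, B = 0L,
                         base_seed = 1L, workers = 1L) {
  stopifnot(n_reps >= 1L)
  set.seed(base_seed)
  rep_seeds <- sample.int(2147483646L, n_reps)

  one <- function(r) {
    run_replication(scenario, n, estimators, seed = rep_seeds[r], B = B)
  }
  rows <- if (workers > 1L) {
    parallel::mclapply(seq_len(n_reps), one, mc.cores = workers)
  } else {
    lapply(seq_len(n_reps), one)
  }

  k <- length(estimators)
  est <- t(vapply(rows, `[[`, numeric(k), "estimate"))
  lo <- t(vapply(rows, `[[`, numeric(k), "ci_lower"))
  hi <- t(vapply(rows, `[[`, numeric(k), "ci_upper"))
  if (k == 1L) {
    est <- matrix(est, ncol = 1L)
    lo <- matrix(lo, ncol = 1L)
    hi <- matrix(hi, ncol = 1L)
  }
  colnames(est) <- colnames(lo) <- colnames(hi) <- estimators

  summ <- do.call(rbind, lapply(seq_len(k), function(j) {
    m <- compute_metrics(est[, j], lo[, j], hi[, j], true_ate = 1)
    cbind(data.frame(estimator = estimators[j], n = n,
                     stringsAsFactors = FALSE), m)
  }))

  structure(
    list(summary = summ, estimates = est, ci_lower = lo, ci_upper = hi,
         scenario_id = scenario$id %||% "custom", n = n, n_reps = n_reps,
         B = B, base_seed = base_seed),
    class = "mr_sim"
  )
}

#' @export
print.mr_sim <- function(x, digits = 3, ...) {
  cat(sprintf("Monte-Carlo scenario %s: n = %d, %d replications, B = %d\n\n",
              x$scenario_id, x$n, x$n_reps, x$B))
  tab <- x$summary
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], round, digits = digits)
  print(tab, row.names = FALSE)
  invisible(x)
}
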