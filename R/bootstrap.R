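#' Nonparametric bootstrap variance and normal-theory confidence interval
#'
#' Resamples the `n` rows of `data` with replacement `B` times and
#' re-evaluates `statistic` on every resample (for model-based estimators
#' this re-runs the entire pipeline, candidate-model refits included).  The
#' variance over successful resamples is
#' `var = sum((est_b - mean(est_b))^2) / (B' - 1)` and the 95% interval is
#' `center +/- 1.96 sqrt(var)`, centred at the original-sample estimate.
#'
#' Resamples on which `statistic` errors, returns `NA`, or which leave a
#' treatment arm empty simply propagate `NA` and are dropped from the
#' variance; if more than 20% of resamples fail for some statistic the
#' bootstrap aborts with an error.
#'
#' @param data Data frame to resample row-wise.
#' @param statistic Function `(data, seed)` returning a numeric scalar or a
#'   named numeric vector (one value per estimator).  The `seed` argument is
#'   a resample-specific sub-seed so any stochastic refit (e.g. network
#'   training) stays reproducible.
#' @param B Number of resamples (at least 2).
#' @param seed Integer seed; the whole bootstrap is deterministic given it.
#' @param center Optional original-sample estimate(s) to centre the interval
#'   at; if omitted, `statistic(data, seed)` is evaluated once to obtain it.
#' @return An object of class `mr_boot`: a list with `B`, `estimates`
#'   (`B x k` matrix of resample values), `center`, `boot_mean`, `variance`,
#'   `se`, `ci_lower`, `ci_upper`, `n_failed` (each length `k`).
#' @examples
#' d <- sim_ate_data(300, seed = 4)
#' bb <- bootstrap_ci(d, function(dd, s) mean(dd$Y[dd$Z == 1]) -
#'                                       mean(dd$Y[dd$Z == 0]), B = 50)
#' bb$se
#' @export
bootstrap_ci <- function(data, statistic, B, seed = 1L, center = NULL) {
  stopifnot(is.data.frame(data), B >= 2L)
  n <- nrow(data)
  if (is.null(center)) center <- statistic(data, subseed(seed, 0L))
  k <- length(center)

  est <- matrix(NA_real_, B, k)
  colnames(est) <- names(center)
  for (b in seq_len(B)) {
    b_seed <- subseed(seed, b)
    set.seed(b_seed)
    idx <- sample.int(n, n, replace = TRUE)
    val <- tryCatch(statistic(data[idx, , drop = FALSE], b_seed),
                    error = function(e) rep(NA_real_, k))
    if (length(val) == k) est[b, ] <- as.numeric(val)
  }

  n_failed <- colSums(is.na(est))
  if (any(n_failed > 0.2 * B)) {
    stop(sprintf("bootstrap failed on more than 20%% of resamples (max %d of %d)",
                 max(n_failed), B))
  }
  variance <- apply(est, 2L, stats::var, na.rm = TRUE)
  se <- sqrt(variance)
  structure(
    list(B = B, estimates = est, center = unname(center),
         boot_mean = unname(colMeans(est, na.rm = TRUE)),
         variance = unname(variance), se = unname(se),
         ci_lower = unname(center - 1.96 * se),
         ci_upper = unname(center + 1.96 * se),
         n_failed = unname(n_failed)),
    class = "mr_boot"
  )
}

#' @export
print.mr_boot <- function(x, ...) {
  cat(sprintf("<mr_boot> B = %d resamples, %d statistic(s)\n",
              x$B, ncol(x$estimates)))
  tab <- data.frame(estimate = x$center, se = x$se,
                    ci_lower = x$ci_lower, ci_upper = x$ci_upper,
                    n_failed = x$n_failed)
  rownames(tab) <- colnames(x$estimates)
  print(round(tab, 4))
  invisible(x)
}
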