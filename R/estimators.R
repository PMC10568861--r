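#' Parse an estimator name
#'
#' Three families are recognised:
#' * `"MR<digits>"` -- multiply robust; one binary digit per candidate model,
#'   PS models first then OR models, each in candidate-list order ("1" =
#'   include).  With three PS and three OR models, `"MR000010"` includes only
#'   the second OR model.
#' * `"IPW.model<k>"` -- inverse probability weighting with the k-th PS model.
#' * `"OR.model<k>"` -- g-computation with the k-th OR model.
#'
#' @param name Estimator name.
#' @param n_ps,n_or Number of candidate PS / OR models available.
#' @return A list with `name`, `type` (`"mr"`, `"ipw"` or `"or"`), and the
#'   included model indices `ps` and `or`.
#' @examples
#' parse_estimator("MR000010", 3, 3)
#' parse_estimator("IPW.model2", 3, 3)
#' @export
parse_estimator <- function(name, n_ps, n_or) {
  stopifnot(is.character(name), length(name) == 1L)
  if (grepl("^MR[01]+$", name)) {
    digits <- as.integer(strsplit(sub("^MR", "", name), "")[[1]])
    if (length(digits) != n_ps + n_or) {
      stop(sprintf("estimator '%s' has %d digits but there are %d candidate models",
                   name, length(digits), n_ps + n_or))
    }
    list(name = name, type = "mr",
         ps = which(digits[seq_len(n_ps)] == 1L),
         or = which(digits[n_ps + seq_len(n_or)] == 1L))
  } else if (grepl("^IPW\\.model[0-9]+$", name)) {
    k <- as.integer(sub("^IPW\\.model", "", name))
    if (k < 1L || k > n_ps) stop(sprintf("no PS model %d for '%s'", k, name))
    list(name = name, type = "ipw", ps = k, or = integer(0))
  } else if (grepl("^OR\\.model[0-9]+$", name)) {
    k <- as.integer(sub("^OR\\.model", "", name))
    if (k < 1L || k > n_or) stop(sprintf("no OR model %d for '%s'", k, name))
    list(name = name, type = "or", ps = integer(0), or = k)
  } else {
    stop(sprintf("unrecognised estimator name '%s'", name))
  }
}

#' Inverse-probability-weighting point estimate
#'
#' Default is the self-normalised (Hajek) form
#' `sum(Z Y / pi) / sum(Z / pi) - sum((1-Z) Y / (1-pi)) / sum((1-Z) / (1-pi))`;
#' `normalize = FALSE` gives the unnormalised Horvitz-Thompson form with
#' divisor `n` in each arm.
#'
#' @param z Binary treatment vector.
#' @param y Outcome vector.
#' @param pi_hat Fitted propensity scores in (0, 1).
#' @param normalize Use the Hajek (self-normalised) form (default `TRUE`).
#' @return The ATE point estimate.
#' @export
ipw_point <- function(z, y, pi_hat, normalize = TRUE) {
  stopifnot(length(z) == length(y), length(y) == length(pi_hat),
            all(pi_hat > 0 & pi_hat < 1))
  if (all(z == 1L) || all(z == 0L)) stop("one treatment arm is empty")
  w1 <- z / pi_hat
  w0 <- (1 - z) / (1 - pi_hat)
  if (normalize) {
    sum(w1 * y) / sum(w1) - sum(w0 * y) / sum(w0)
  } else {
    mean(w1 * y) - mean(w0 * y)
  }
}

#' G-computation point estimate
#'
#' @param m1,m0 Counterfactual outcome predictions under treatment / control
#'   for all `n` subjects.
#' @return `mean(m1 - m0)`.
#' @export
or_point <- function(m1, m0) {
  stopifnot(length(m1) == length(m0))
  mean(m1 - m0)
}

#' Multiply robust point estimate
#'
#' Solves the empirical-likelihood calibration problem independently in each
#' arm for the selected candidate models and returns the weighted difference
#' `sum_i w_i Y_i - sum_j w_j Y_j` (treated minus control).  With no models
#' selected both weight vectors are uniform and the estimate reduces exactly
#' to the difference of arm means.  A convex-hull failure in either arm fails
#' the whole estimate (`mrate_convex_hull_error`).
#'
#' @param fc An `mr_candidates` object.
#' @param z,y Treatment and outcome vectors of the same dataset.
#' @param ps,or Integer indices of the included PS / OR models.
#' @return A list: `estimate`, and the per-arm `mr_el` solutions
#'   `el_treated`, `el_control`.
#' @export
mr_point <- function(fc, z, y, ps = integer(0), or = integer(0)) {
  G1 <- el_constraints(fc, z, "treated", ps = ps, or = or)
  G0 <- el_constraints(fc, z, "control", ps = ps, or = or)
  s1 <- el_weights(G1)
  s0 <- el_weights(G0)
  est <- sum(s1$weights * y[z == 1L]) - sum(s0$weights * y[z == 0L])
  list(estimate = est, el_treated = s1, el_control = s0)
}

needed_indices <- function(specs, n_ps, n_or) {
  list(ps = sort(unique(unlist(lapply(specs, `[[`, "ps")))),
       or = sort(unique(unlist(lapply(specs, `[[`, "or")))))
}

# Point estimates for a list of parsed estimator specs given fitted
# candidates; convex-hull failures yield NA with a recorded message.
estimate_all <- function(fc, z, y, specs, normalize = TRUE) {
  out <- vapply(specs, function(sp) {
    switch(sp$type,
      ipw = ipw_point(z, y, fc$ps_hat[, sp$ps], normalize = normalize),
      or = or_point(fc$m1_hat[, sp$or], fc$m0_hat[, sp$or]),
      mr = tryCatch(mr_point(fc, z, y, sp$ps, sp$or)$estimate,
                    mrate_convex_hull_error = function(e) NA_real_)
    )
  }, numeric(1))
  names(out) <- vapply(specs, `[[`, "", "name")
  out
}

#' Multiply robust average-treatment-effect estimation
#'
#' The main fitting function.  Fits the candidate propensity-score and
#' outcome-regression models once on the full sample, then computes every
#' requested estimator: multiply robust (`"MR..."` -- empirical-likelihood
#' calibration weights against any subset of the candidates), inverse
#' probability weighting (`"IPW.modelK"`) and g-computation (`"OR.modelK"`).
#' With `B > 0` a nonparametric bootstrap (resampling rows with replacement
#' and re-running the entire pipeline, networks included) supplies a standard
#' error and a normality-based 95% confidence interval centred at the
#' original-sample estimate.
#'
#' The MR estimator is consistent if any one included candidate model is
#' correctly specified.  Only the candidate models some requested estimator
#' actually uses are fitted.
#'
#' @param data Data frame with the treatment, outcome and covariate columns.
#' @param ps_models,or_models Lists of candidate [model_specs].
#' @param estimators Character vector of estimator names (see
#'   [parse_estimator()]); default: the MR estimator using every candidate.
#' @param treatment,outcome Column names (defaults `"Z"`, `"Y"`).
#' @param B Bootstrap resamples (0 = no interval).
#' @param seed Integer seed for network training and the bootstrap.
#' @param ipw_normalize Use Hajek IPW (default) or Horvitz-Thompson.
#' @return An object of class `mr_ate` with methods `print`, `summary`,
#'   `coef`, `confint` and `plot`.  Component `estimates` is a data frame
#'   with one row per estimator (`estimate`, `se`, `ci_lower`, `ci_upper`,
#'   `boot_failed`).
#' @examples
#' d <- sim_ate_data(400, seed = 2)
#' fit <- mr_ate(d,
#'   ps_models = list(ps_glm(~ X1 + X2 + X3 + X4 + X5 + X6 + X7)),
#'   or_models = list(or_lm(~ X1 + X2 + X3 + X8 + X9 + X10 +
#'                            I(X1^2) + I(X2^2))),
#'   estimators = c("MR01", "IPW.model1", "OR.model1"))
#' coef(fit)
#' @export
mr_ate <- function(data, ps_models = list(), or_models = list(),
                   estimators = NULL, treatment = "Z", outcome = "Y",
                   B = 0L, seed = 1L, ipw_normalize = TRUE) {
  data <- validate_dataset(data, treatment, outcome)
  z <- data[[treatment]]
  y <- data[[outcome]]
  L <- length(ps_models)
  K <- length(or_models)
  if (is.null(estimators)) {
    estimators <- paste0("MR", strrep("1", L + K))
  }
  specs <- lapply(estimators, parse_estimator, n_ps = L, n_or = K)
  need <- needed_indices(specs, L, K)

  fc <- fit_candidates(data, ps_models, or_models, treatment, outcome,
                       seed = seed, ps_fit = need$ps, or_fit = need$or)
  est <- estimate_all(fc, z, y, specs, normalize = ipw_normalize)

  res <- data.frame(estimator = names(est), estimate = unname(est),
                    se = NA_real_, ci_lower = NA_real_, ci_upper = NA_real_,
                    boot_failed = NA_integer_, stringsAsFactors = FALSE)

  boot <- NULL
  if (B > 0L) {
    boot <- bootstrap_ci(
      data,
      statistic = function(d, b_seed) {
        fcb <- fit_candidates(d, ps_models, or_models, treatment, outcome,
                              seed = b_seed, ps_fit = need$ps,
                              or_fit = need$or)
        estimate_all(fcb, d[[treatment]], d[[outcome]], specs,
                     normalize = ipw_normalize)
      },
      B = B, seed = seed, center = est
    )
    res$se <- boot$se
    res$ci_lower <- boot$ci_lower
    res$ci_upper <- boot$ci_upper
    res$boot_failed <- boot$n_failed
  }

  structure(
    list(estimates = res, candidates = fc, bootstrap = boot,
         n = nrow(data), n1 = sum(z == 1L), n0 = sum(z == 0L),
         B = B, seed = seed, treatment = treatment, outcome = outcome,
         call = match.call()),
    class = "mr_ate"
  )
}

#' @export
print.mr_ate <- function(x, digits = 3, ...) {
  cat("Multiply robust ATE estimation\n")
  cat(sprintf("  n = %d (treated %d, control %d)", x$n, x$n1, x$n0))
  if (x$B > 0L) cat(sprintf(", bootstrap B = %d", x$B))
  cat("\n\n")
  tab <- x$estimates
  tab[-1] <- lapply(tab[-1], round, digits = digits)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
summary.mr_ate <- function(object, ...) {
  structure(list(fit = object), class = "summary.mr_ate")
}

#' @export
print.summary.mr_ate <- function(x, ...) {
  print(x$fit)
  fc <- x$fit$candidates
  cat(sprintf("\nCandidate models fitted: %d PS, %d OR\n",
              sum(fc$ps_fitted), sum(fc$or_fitted)))
  invisible(x)
}

#' @export
coef.mr_ate <- function(object, ...) {
  stats::setNames(object$estimates$estimate, object$estimates$estimator)
}

#' @export
confint.mr_ate <- function(object, parm, level = 0.95, ...) {
  est <- object$estimates
  if (is.null(object$bootstrap)) {
    stop("no bootstrap was run; refit with B > 0 to obtain intervals")
  }
  if (level != 0.95) {
    q <- stats::qnorm(1 - (1 - level) / 2)
    ci <- cbind(est$estimate - q * est$se, est$estimate + q * est$se)
  } else {
    ci <- cbind(est$ci_lower, est$ci_upper)
  }
  rownames(ci) <- est$estimator
  colnames(ci) <- sprintf("%.1f %%", 100 * c((1 - level) / 2,
                                             1 - (1 - level) / 2))
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' @export
plot.mr_ate <- function(x, ...) {
  est <- x$estimates
  k <- nrow(est)
  has_ci <- !all(is.na(est$ci_lower))
  xlim <- range(c(est$estimate, est$ci_lower, est$ci_upper), na.rm = TRUE)
  graphics::plot(est$estimate, seq_len(k), yaxt = "n", ylab = "",
                 xlab = "ATE estimate", xlim = xlim, pch = 19, ...)
  graphics::axis(2, at = seq_len(k), labels = est$estimator, las = 1,
                 cex.axis = 0.8)
  if (has_ci) {
    graphics::segments(est$ci_lower, seq_len(k), est$ci_upper, seq_len(k))
  }
  invisible(x)
}
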