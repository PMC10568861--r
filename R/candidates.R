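#' Candidate model specifications
#'
#' Constructors for the candidate propensity-score (PS) and outcome-regression
#' (OR) working models the multiply robust estimator calibrates against.
#' Each takes a one-sided formula naming covariate terms; the usual formula
#' grammar (`I(X1^2)`, `X1:X2`, ...) is available.  Outcome models always
#' receive the treatment indicator as an additional regressor/input, so their
#' formulas list covariates only; counterfactual predictions are obtained by
#' evaluating the fitted model at treatment 1 and 0.
#'
#' * `ps_glm()`: maximum-likelihood logistic regression (with intercept).
#' * `ps_nnet()`: single-hidden-layer neural network classifier with
#'   `size` hidden units (entropy loss, logistic output).
#' * `or_lm()`: ordinary least squares (with intercept), fit on the full
#'   sample with the treatment as a regressor.
#' * `or_nnet()`: single-hidden-layer neural network regression
#'   (least-squares loss, linear output), treatment included as an input.
#'
#' Networks are fit with [nnet::nnet()] and its default optimiser settings
#' (BFGS, `maxit = 100`, no weight decay, uniform random initial weights);
#' training is made reproducible by seeding each fit from the seed passed to
#' [fit_candidates()].
#'
#' @param formula One-sided formula of covariate terms, e.g. `~ X1 + I(X1^2)`.
#' @param size Number of hidden units (default 4).
#' @param maxit Maximum optimiser iterations.
#' @param decay Weight-decay penalty.
#' @return An object of class `mr_model_spec`.
#' @examples
#' ps_glm(~ X1 + X2 + X3)
#' or_nnet(~ X1 + X2)
#' @name model_specs
NULL

new_model_spec <- function(target, form, formula, size = NULL,
                           maxit = NULL, decay = NULL) {
  stopifnot(inherits(formula, "formula"), length(formula) == 2L)
  structure(
    list(target = target, form = form, formula = formula,
         size = size, maxit = maxit, decay = decay),
    class = "mr_model_spec"
  )
}

#' @rdname model_specs
#' @export
ps_glm <- function(formula) new_model_spec("ps", "parametric", formula)

#' @rdname model_specs
#' @export
ps_nnet <- function(formula, size = 4L, maxit = 100L, decay = 0) {
  new_model_spec("ps", "network", formula, size, maxit, decay)
}

#' @rdname model_specs
#' @export
or_lm <- function(formula) new_model_spec("or", "parametric", formula)

#' @rdname model_specs
#' @export
or_nnet <- function(formula, size = 4L, maxit = 100L, decay = 0) {
  new_model_spec("or", "network", formula, size, maxit, decay)
}

#' @export
print.mr_model_spec <- function(x, ...) {
  cat(sprintf("<%s %s model> %s\n",
              if (x$form == "network") sprintf("%d-unit network", x$size)
              else x$form,
              toupper(x$target), deparse(x$formula)))
  invisible(x)
}

# Deterministic sub-seed derivation: keeps every derived seed in [1, 2^31 - 2]
# so replications, model fits and bootstrap resamples draw from independent,
# reproducible streams.
subseed <- function(seed, k) {
  s <- (as.double(seed) * 48271 + as.double(k) * 16807) %% 2147483646
  as.integer(s) + 1L
}

clip_prob <- function(p, eps = 1e-6) pmin(pmax(p, eps), 1 - eps)

fit_one_model <- function(spec, data, treatment, outcome, seed, index) {
  label <- sprintf("%s model %d", toupper(spec$target), index)
  if (spec$target == "ps") {
    f <- stats::update(spec$formula,
                       stats::as.formula(paste(treatment, "~ .")))
  } else {
    f <- stats::update(spec$formula,
                       stats::as.formula(paste(outcome, "~ . +", treatment)))
  }
  fit <- tryCatch({
    if (spec$form == "parametric" && spec$target == "ps") {
      m <- stats::glm(f, family = stats::binomial(), data = data)
      if (!m$converged) stop("IRLS did not converge (possible separation)")
      m
    } else if (spec$form == "parametric") {
      m <- stats::lm(f, data = data)
      if (m$rank < length(stats::coef(m))) {
        warning(sprintf("%s: rank-deficient design; aliased terms dropped",
                        label), call. = FALSE)
      }
      m
    } else {
      set.seed(subseed(seed, index))
      if (spec$target == "ps") {
        nnet::nnet(f, data = data, size = spec$size, maxit = spec$maxit,
                   decay = spec$decay, entropy = TRUE, trace = FALSE)
      } else {
        nnet::nnet(f, data = data, size = spec$size, maxit = spec$maxit,
                   decay = spec$decay, linout = TRUE, trace = FALSE)
      }
    }
  }, error = function(e) {
    stop(sprintf("fitting %s failed: %s", label, conditionMessage(e)),
         call. = FALSE)
  })
  fit
}

predict_ps <- function(fit, data) {
  p <- if (inherits(fit, "glm")) {
    stats::predict(fit, newdata = data, type = "response")
  } else {
    drop(stats::predict(fit, newdata = data, type = "raw"))
  }
  clip_prob(as.numeric(p))
}

predict_or <- function(fit, data, treatment, z) {
  nd <- data
  nd[[treatment]] <- z
  p <- if (inherits(fit, "lm")) {
    suppressWarnings(stats::predict(fit, newdata = nd))
  } else {
    drop(stats::predict(fit, newdata = nd))
  }
  as.numeric(p)
}

#' Fit the candidate model set and evaluate calibration targets
#'
#' Fits every requested candidate model on the full sample and evaluates, for
#' each subject, the fitted propensity `pi^l(X_i)` and the counterfactual
#' outcome predictions `m_1^k(X_i)`, `m_0^k(X_i)` (the OR fit evaluated at
#' treatment 1 and 0).  Also computes the population calibration targets:
#' `theta1[l] = mean(pi^l)`, `theta0[l] = 1 - theta1[l]`,
#' `eta1[k] = mean(m1^k)` and `eta0[k] = mean(m0^k)` -- all averages over the
#' full sample of `n`, not arm-restricted.
#'
#' @param data A data frame containing the treatment, outcome and covariates.
#' @param ps_models,or_models Lists of [model_specs] (either may be empty).
#' @param treatment,outcome Column names of the binary treatment and the
#'   numeric outcome.
#' @param seed Integer seed governing network training.
#' @param ps_fit,or_fit Optional integer vectors naming which models to
#'   actually fit (defaults to all); unfitted columns are `NA`.  Used to skip
#'   expensive fits that no requested estimator needs.
#' @return An object of class `mr_candidates` with elements `ps_hat`
#'   (`n x L` matrix), `m1_hat`, `m0_hat` (`n x K`), `theta1`, `theta0`,
#'   `eta1`, `eta0`, and bookkeeping fields.
#' @examples
#' d <- sim_ate_data(300, seed = 1)
#' fc <- fit_candidates(d, ps_models = list(ps_glm(~ X1 + X2)),
#'                      or_models = list(or_lm(~ X1 + X2)))
#' fc$theta1 + fc$theta0  # exactly 1
#' @export
fit_candidates <- function(data, ps_models = list(), or_models = list(),
                           treatment = "Z", outcome = "Y", seed = 1L,
                           ps_fit = NULL, or_fit = NULL) {
  stopifnot(is.data.frame(data), length(ps_models) + length(or_models) >= 1L)
  n <- nrow(data)
  L <- length(ps_models)
  K <- length(or_models)
  if (is.null(ps_fit)) ps_fit <- seq_len(L)
  if (is.null(or_fit)) or_fit <- seq_len(K)

  ps_hat <- matrix(NA_real_, n, L,
                   dimnames = list(NULL, if (L) paste0("ps", seq_len(L))))
  m1_hat <- matrix(NA_real_, n, K,
                   dimnames = list(NULL, if (K) paste0("or", seq_len(K))))
  m0_hat <- m1_hat
  ps_fits <- vector("list", L)
  or_fits <- vector("list", K)

  for (l in ps_fit) {
    spec <- ps_models[[l]]
    stopifnot(spec$target == "ps")
    fit <- fit_one_model(spec, data, treatment, outcome, seed, l)
    ps_fits[[l]] <- fit
    ps_hat[, l] <- predict_ps(fit, data)
  }
  for (k in or_fit) {
    spec <- or_models[[k]]
    stopifnot(spec$target == "or")
    fit <- fit_one_model(spec, data, treatment, outcome, seed, L + k)
    or_fits[[k]] <- fit
    m1_hat[, k] <- predict_or(fit, data, treatment, 1)
    m0_hat[, k] <- predict_or(fit, data, treatment, 0)
  }

  theta1 <- colMeans(ps_hat)
  structure(
    list(ps_hat = ps_hat, m1_hat = m1_hat, m0_hat = m0_hat,
         theta1 = theta1, theta0 = 1 - theta1,
         eta1 = colMeans(m1_hat), eta0 = colMeans(m0_hat),
         ps_fitted = seq_len(L) %in% ps_fit,
         or_fitted = seq_len(K) %in% or_fit,
         ps_fits = ps_fits, or_fits = or_fits,
         n = n, treatment = treatment, outcome = outcome),
    class = "mr_candidates"
  )
}

#' @export
print.mr_candidates <- function(x, ...) {
  cat(sprintf("<mr_candidates> n = %d, %d PS model(s), %d OR model(s)\n",
              x$n, ncol(x$ps_hat), ncol(x$m1_hat)))
  if (length(x$theta1)) {
    cat("  theta1:", format(x$theta1, digits = 4), "\n")
  }
  if (length(x$eta1)) {
    cat("  eta1:  ", format(x$eta1, digits = 4), "\n")
  }
  invisible(x)
}
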