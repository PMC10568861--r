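#' Population correlation matrix of the simulated covariates
#'
#' The ten covariates are marginally standard normal with
#' `corr(X1, X5) = corr(X4, X9) = 0.9`, `corr(X2, X6) = corr(X3, X8) = 0.2`
#' and all other pairs uncorrelated.  With this block structure the matrix is
#' positive definite (smallest eigenvalue `1 - 0.9 = 0.1`).
#'
#' @return A 10 x 10 correlation matrix.
#' @export
sim_correlation <- function() {
  R <- diag(10)
  R[1, 5] <- R[5, 1] <- 0.9
  R[4, 9] <- R[9, 4] <- 0.9
  R[2, 6] <- R[6, 2] <- 0.2
  R[3, 8] <- R[8, 3] <- 0.2
  dimnames(R) <- list(paste0("X", 1:10), paste0("X", 1:10))
  R
}

# PS linear predictor has no intercept; outcome model has intercept -3.85,
# a quadratic in X1 and X2, and unit treatment effect.
.ps_coef <- c(0.8, -0.25, 0.6, -0.4, -0.8, -0.5, 0.7, 0, 0, 0)
.or_coef <- c(0.3, -0.36, -0.73, -0.2, 0, 0, 0, 0.71, 0.19, 0.26)

#' Draw correlated standard-normal covariates
#'
#' Draws `n` i.i.d. rows from a 10-dimensional zero-mean normal with the
#' correlation matrix of [sim_correlation()].  Uses the current RNG state.
#'
#' @param n Number of rows.
#' @return An `n x 10` matrix with columns `X1` ... `X10`.
#' @export
sim_covariates <- function(n) {
  stopifnot(is.numeric(n), length(n) == 1L, n >= 1)
  R <- sim_correlation()
  stopifnot(min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) > 0)
  Z <- matrix(stats::rnorm(n * 10L), nrow = n, ncol = 10L)
  X <- Z %*% chol(R)
  colnames(X) <- colnames(R)
  X
}

#' True propensity score of the simulated design
#'
#' `logit P(Z = 1 | X) = 0.8 X1 - 0.25 X2 + 0.6 X3 - 0.4 X4 - 0.8 X5
#'  - 0.5 X6 + 0.7 X7` (no intercept), giving a treatment prevalence of
#' roughly 50%.
#'
#' @param X Covariate matrix with at least 7 columns.
#' @return Vector of treatment probabilities.
#' @export
sim_propensity <- function(X) {
  X <- as.matrix(X)
  stopifnot(ncol(X) >= 7L)
  drop(stats::plogis(X[, 1:7, drop = FALSE] %*% .ps_coef[1:7]))
}

#' Draw treatment assignments from the true propensity model
#'
#' @inheritParams sim_propensity
#' @return Binary vector of length `nrow(X)`.
#' @export
sim_treatment <- function(X) {
  stats::rbinom(nrow(as.matrix(X)), 1L, sim_propensity(X))
}

#' Conditional mean outcome of the simulated design
#'
#' `E[Y | X, Z] = -3.85 + 0.3 X1 - 0.36 X2 - 0.73 X3 - 0.2 X4 + 0.71 X8
#'  + 0.19 X9 + 0.26 X10 + 0.3 X1^2 - 0.36 X2^2 + Z`, so the subject-level
#' causal contrast is exactly 1 for every covariate value.
#'
#' @param X Covariate matrix with 10 columns.
#' @param Z Binary treatment vector.
#' @return Vector of conditional means.
#' @export
sim_outcome_mean <- function(X, Z) {
  X <- as.matrix(X)
  stopifnot(ncol(X) == 10L, nrow(X) == length(Z))
  -3.85 + drop(X %*% .or_coef) + 0.3 * X[, 1]^2 - 0.36 * X[, 2]^2 + Z
}

#' Draw outcomes with standard-normal noise
#'
#' @inheritParams sim_outcome_mean
#' @return Numeric outcome vector `Y = E[Y | X, Z] + eps`, `eps ~ N(0, 1)`
#'   independent of `X` and `Z`.
#' @export
sim_outcome <- function(X, Z) {
  sim_outcome_mean(X, Z) + stats::rnorm(length(Z))
}

#' Simulate a full dataset with known true ATE
#'
#' Generates covariates, treatment and outcome in one seeded RNG stream:
#' the true average treatment effect is exactly 1 by construction.
#'
#' @param n Sample size (at least 2).
#' @param seed Optional integer seed; if supplied the draw is reproducible.
#' @return A `data.frame` with columns `X1` ... `X10`, `Z`, `Y` and attribute
#'   `true_ate = 1`.  Errors if either treatment arm is empty.
#' @examples
#' d <- sim_ate_data(200, seed = 1)
#' table(d$Z)
#' @export
sim_ate_data <- function(n, seed = NULL) {
  stopifnot(is.numeric(n), length(n) == 1L, n >= 2)
  if (!is.null(seed)) set.seed(seed)
  X <- sim_covariates(n)
  Z <- sim_treatment(X)
  if (all(Z == 1L) || all(Z == 0L)) {
    stop("simulated dataset has an empty treatment arm (n = ", n,
         "); increase n")
  }
  Y <- sim_outcome(X, Z)
  out <- data.frame(X, Z = Z, Y = Y)
  attr(out, "true_ate") <- 1
  out
}
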