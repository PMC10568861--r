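#' Build the centered constraint matrix for one treatment arm
#'
#' For the treated arm the constraint vector of subject `i` is
#' `(pi^l(X_i) - theta1^l, ..., m1^k(X_i) - eta1^k, ...)`; for the control arm
#' `((1 - pi^l(X_j)) - theta0^l, ..., m0^k(X_j) - eta0^k, ...)`.  PS columns
#' come first, then OR columns, each in candidate-list order.  The empirical
#' likelihood weights of the arm are calibrated so that every column of the
#' returned matrix averages to zero under the weights.
#'
#' @param fc An `mr_candidates` object evaluated on the same data.
#' @param z Binary treatment vector of the dataset.
#' @param arm `"treated"` or `"control"`.
#' @param ps,or Integer indices of the PS / OR models to include
#'   (default: all fitted).
#' @return An `n_arm x d` matrix with attributes `arm`, `ps`, `or`.
#' @export
el_constraints <- function(fc, z, arm = c("treated", "control"),
                           ps = NULL, or = NULL) {
  arm <- match.arg(arm)
  stopifnot(inherits(fc, "mr_candidates"), length(z) == fc$n)
  if (is.null(ps)) ps <- which(fc$ps_fitted)
  if (is.null(or)) or <- which(fc$or_fitted)
  idx <- if (arm == "treated") which(z == 1L) else which(z == 0L)
  if (length(idx) == 0L) stop("the ", arm, " arm is empty")

  if (arm == "treated") {
    Gp <- sweep(fc$ps_hat[idx, ps, drop = FALSE], 2L, fc$theta1[ps])
    Go <- sweep(fc$m1_hat[idx, or, drop = FALSE], 2L, fc$eta1[or])
  } else {
    Gp <- sweep(1 - fc$ps_hat[idx, ps, drop = FALSE], 2L, fc$theta0[ps])
    Go <- sweep(fc$m0_hat[idx, or, drop = FALSE], 2L, fc$eta0[or])
  }
  G <- cbind(Gp, Go)
  if (anyNA(G)) stop("constraint matrix references unfitted candidate models")
  structure(G, arm = arm, ps = ps, or = or)
}

#' Solve the empirical-likelihood dual for one arm
#'
#' Maximising `prod(w_i)` subject to `w_i >= 0`, `sum(w_i) = 1` and the
#' calibration constraints `sum_i w_i G[i, ] = 0` has the dual solution
#' `w_i = 1 / (n (1 + rho' G[i, ]))`, where the Lagrange multipliers `rho`
#' minimise the convex dual `F(rho) = -sum_i log(1 + rho' G[i, ])` over the
#' region where every `1 + rho' G[i, ] > 0`.  The gradient of `F` is (minus
#' `n` times) the stationarity condition `(1/n) sum_i G[i, ] / (1 + rho'
#' G[i, ]) = 0`, so Newton's method on the dual solves it with guaranteed
#' descent.
#'
#' Implementation notes: iteration starts at `rho = 0`; each Newton step is
#' halved until the iterate keeps every `1 + rho' G[i, ]` above a feasibility
#' buffer of `1 / n_arm^2` and does not increase `F`.  Near-collinear
#' constraint columns are detected by a rank-revealing QR and dropped before
#' solving (their multipliers are reported as 0); a singular Newton system is
#' regularised with a tiny ridge.  If no feasible descent step exists or the
#' iteration cap is reached, the calibration targets lie outside (or on the
#' boundary of) the convex hull of the arm's model values and no solution
#' exists: `converged` is `FALSE`.
#'
#' @param G Constraint matrix from [el_constraints()] (rows = arm subjects).
#' @param tol Convergence tolerance on the max-norm of the scaled gradient
#'   `(1/n) sum_i G[i, ] / (1 + rho' G[i, ])`.
#' @param maxit Newton iteration cap.
#' @return A list of class `mr_el`: `rho` (length `ncol(G)`, zeros for
#'   dropped columns), `weights` (positive, summing to 1), `converged`,
#'   `iterations`, `max_constraint_residual` (over retained columns), and
#'   `dropped` (indices of dropped near-collinear columns) and `f_path`
#'   (dual objective at each accepted iterate; non-increasing).
#' @export
el_solve <- function(G, tol = 1e-8, maxit = 50L) {
  G <- as.matrix(G)
  n <- nrow(G)
  d <- ncol(G)
  stopifnot(n >= 1L)
  if (d > 0L && n <= d) {
    warning("fewer arm subjects than constraints (n_arm = ", n,
            ", d = ", d, "); the EL solution is unlikely to exist")
  }

  keep <- seq_len(d)
  dropped <- integer(0)
  if (d > 0L) {
    qrG <- qr(G, tol = max(1e-10, 1e-10 * max(abs(G))))
    if (qrG$rank < d) {
      keep <- sort(qrG$pivot[seq_len(qrG$rank)])
      dropped <- setdiff(seq_len(d), keep)
    }
  }
  Gk <- G[, keep, drop = FALSE]
  dk <- ncol(Gk)
  rho <- numeric(dk)
  buffer <- 1 / n^2

  iter <- 0L
  converged <- FALSE
  f_path <- -sum(log(pmax(drop(1 + Gk %*% rho), .Machine$double.xmin)))
  repeat {
    r <- drop(1 + Gk %*% rho)
    g_scaled <- if (dk) colSums(Gk / r) / n else numeric(0)
    # convergence is judged on the weight-normalised residual sum_i w_i G_i:
    # the raw gradient also vanishes when the dual is unbounded (targets
    # outside the convex hull), the normalised residual does not
    g_resid <- if (dk) colSums(Gk / r) / sum(1 / r) else numeric(0)
    if (dk == 0L || max(abs(g_resid)) <= tol) {
      converged <- TRUE
      break
    }
    if (iter >= maxit) break
    Fcur <- -sum(log(r))
    H <- crossprod(Gk / r)  # Hessian of the dual, positive semi-definite
    delta <- tryCatch(solve(H, n * g_scaled), error = function(e) {
      solve(H + diag(1e-10 * max(diag(H)), dk), n * g_scaled)
    })
    # backtracking: feasibility buffer + monotone descent
    alpha <- 1
    ok <- FALSE
    for (h in 1:40) {
      cand <- rho + alpha * delta
      rc <- drop(1 + Gk %*% cand)
      # descent with a rounding-level slack so full Newton steps are not
      # rejected once F's decrease falls below double precision
      if (min(rc) >= buffer &&
          -sum(log(rc)) <= Fcur + 1e-11 * (1 + abs(Fcur))) {
        ok <- TRUE
        break
      }
      alpha <- alpha / 2
    }
    if (!ok) break  # no feasible descent: hull condition violated
    rho <- rho + alpha * delta
    f_path <- c(f_path, -sum(log(drop(1 + Gk %*% rho))))
    iter <- iter + 1L
  }

  r <- drop(1 + Gk %*% rho)
  w <- 1 / (n * r)
  w <- w / sum(w)  # removes O(tol) drift so sum(w) == 1 exactly
  rho_full <- numeric(d)
  rho_full[keep] <- rho
  resid <- if (dk) max(abs(colSums(Gk * w))) else 0
  structure(
    list(rho = rho_full, weights = w, converged = converged,
         iterations = iter, max_constraint_residual = resid,
         dropped = dropped, n_arm = n, f_path = f_path),
    class = "mr_el"
  )
}

#' Empirical-likelihood calibration weights for one arm
#'
#' Wrapper around [el_solve()] that verifies the solution invariants
#' (positive weights summing to 1, every retained constraint satisfied to
#' `1e-6`) and raises a `mrate_convex_hull_error` when the solver cannot
#' converge -- i.e. when the calibration targets lie outside the convex hull
#' of the arm's candidate-model values, so no valid weight vector exists.
#'
#' @inheritParams el_solve
#' @return A converged `mr_el` object.
#' @export
el_weights <- function(G, tol = 1e-8, maxit = 50L) {
  sol <- el_solve(G, tol = tol, maxit = maxit)
  if (!sol$converged) {
    stop(errorCondition(
      sprintf(paste0("empirical-likelihood solve failed for the %s arm ",
                     "(d = %d, n_arm = %d): calibration targets outside the ",
                     "convex hull of the model values"),
              attr(G, "arm") %||% "requested", ncol(as.matrix(G)), sol$n_arm),
      class = c("mrate_convex_hull_error", "error", "condition")
    ))
  }
  stopifnot(all(sol$weights > 0),
            abs(sum(sol$weights) - 1) <= 1e-8,
            sol$max_constraint_residual <= 1e-6)
  sol
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.mr_el <- function(x, ...) {
  cat(sprintf(
    "<mr_el> n_arm = %d, d = %d, converged = %s in %d iteration(s)\n",
    x$n_arm, length(x$rho), x$converged, x$iterations))
  cat(sprintf("  max constraint residual: %.2e", x$max_constraint_residual))
  if (length(x$dropped)) {
    cat(sprintf(" (dropped collinear column(s): %s)",
                paste(x$dropped, collapse = ", ")))
  }
  cat("\n")
  invisible(x)
}
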