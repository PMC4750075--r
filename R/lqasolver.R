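# Solver for the weighted fused LASSO objective
#
#   minimize  || Y - X beta ||_2^2
#           + lambda1 * || D1 beta ||_1
#           + lambda2 * || D2 beta ||_1
#
# by local quadratic approximation (LQA): each |u| is majorized at the
# current iterate by u^2 / (2 sqrt(u0^2 + eps)) + const, giving a ridge
# system solved by Cholesky decomposition,
#
#   (X'X + (lambda1/2) D1' A1 D1 + (lambda2/2) D2' A2 D2) beta = X'Y,
#
# with A diagonal, A_r = 1 / sqrt((d_r' beta_prev)^2 + eps).  This is a
# majorize-minimize scheme, so the eps-smoothed objective decreases
# monotonically.  An independent ADMM solver for the same convex program
# is provided as a verification oracle.

#' Solver options
#'
#' @param lqa_epsilon Smoothing constant in |u| ~ sqrt(u^2 + eps).
#' @param max_iterations Maximum LQA iterations.
#' @param tolerance Convergence tolerance on the max coefficient change.
#' @param zero_threshold Coefficients below this magnitude are reported
#'   as exact zeros.
#' @return A `solver_options` list.
#' @export
solver_options <- function(lqa_epsilon = 1e-10, max_iterations = 500L,
                           tolerance = 1e-8, zero_threshold = 1e-6) {
  stopifnot(lqa_epsilon > 0, tolerance > 0, zero_threshold >= 0,
            max_iterations >= 1L)
  structure(list(lqa_epsilon = lqa_epsilon,
                 max_iterations = as.integer(max_iterations),
                 tolerance = tolerance,
                 zero_threshold = zero_threshold),
            class = "solver_options")
}

#' Penalized objective value
#'
#' @param beta Coefficient vector of length k * P.
#' @param sr A `stacked_regression`.
#' @param lambda1,lambda2 Non-negative penalty strengths.
#' @return `||Y - X beta||^2 + lambda1 ||D1 beta||_1 + lambda2 ||D2 beta||_1`.
#' @export
objective <- function(beta, sr, lambda1, lambda2) {
  if (length(beta) != ncol(sr$X)) {
    stopf("beta has length %d, expected %d", length(beta), ncol(sr$X))
  }
  stopifnot(lambda1 >= 0, lambda2 >= 0)
  r <- sr$Y - as.numeric(sr$X %*% beta)
  pen1 <- lambda1 * sum(abs(sr$D1 %*% beta))
  pen2 <- if (nrow(sr$D2) > 0L) lambda2 * sum(abs(sr$D2 %*% beta)) else 0
  sum(r^2) + pen1 + pen2
}

# eps-smoothed objective used to monitor LQA monotonicity
objective_smoothed <- function(beta, sr, lambda1, lambda2, eps) {
  r <- sr$Y - as.numeric(sr$X %*% beta)
  pen1 <- lambda1 * sum(sqrt(as.numeric(sr$D1 %*% beta)^2 + eps))
  pen2 <- if (nrow(sr$D2) > 0L) {
    lambda2 * sum(sqrt(as.numeric(sr$D2 %*% beta)^2 + eps))
  } else 0
  sum(r^2) + pen1 + pen2
}

# Cholesky solve with escalating jitter for near-singular systems
chol_solve <- function(M, b) {
  jit <- 0
  base <- mean(diag(M))
  if (!is.finite(base) || base <= 0) base <- 1
  for (i in 0:6) {
    R <- tryCatch(chol(M + diag(jit, nrow(M))), error = function(e) NULL)
    if (!is.null(R)) return(backsolve(R, backsolve(R, b, transpose = TRUE)))
    jit <- if (jit == 0) 1e-12 * base else jit * 100
  }
  stopf("penalized normal equations are numerically singular")
}

#' Fit the fused LASSO by local quadratic approximation
#'
#' Starts from a ridge solution (penalty `1e-3 * trace(X'X) / (kP)`),
#' iterates the LQA ridge system via Cholesky solves, and stops when the
#' maximum coefficient change drops below the tolerance.  Coefficients
#' smaller than the zero threshold are reported as exact zeros.
#'
#' @param sr A `stacked_regression`.
#' @param lambda1,lambda2 Non-negative penalties.
#' @param opts A `solver_options`.
#' @return A `fit_result`: list with `beta`, `lambda1`, `lambda2`,
#'   `iterations`, `converged`, `objective`, `response`.
#' @export
fit_lqa <- function(sr, lambda1, lambda2, opts = solver_options()) {
  stopifnot(lambda1 >= 0, lambda2 >= 0)
  X <- sr$X
  XtX <- crossprod(X)
  XtY <- crossprod(X, sr$Y)
  p <- ncol(X)
  eps <- opts$lqa_epsilon

  d1 <- diag(sr$D1)          # D1 is diagonal by construction
  has_fuse <- nrow(sr$D2) > 0L && lambda2 > 0

  ridge <- 1e-3 * sum(diag(XtX)) / p
  if (!is.finite(ridge) || ridge <= 0) ridge <- 1e-3
  beta <- as.numeric(chol_solve(XtX + diag(ridge, p), XtY))

  converged <- FALSE
  iters <- 0L
  for (it in seq_len(opts$max_iterations)) {
    iters <- it
    a1 <- 1 / sqrt((d1 * beta)^2 + eps)
    M <- XtX
    if (lambda1 > 0) M <- M + diag(lambda1 / 2 * d1^2 * a1, p)
    if (has_fuse) {
      u2 <- as.numeric(sr$D2 %*% beta)
      a2 <- 1 / sqrt(u2^2 + eps)
      M <- M + lambda2 / 2 * crossprod(sr$D2 * sqrt(a2))
    }
    beta_new <- as.numeric(chol_solve(M, XtY))
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    if (delta < opts$tolerance) {
      converged <- TRUE
      break
    }
  }

  beta[abs(beta) < opts$zero_threshold] <- 0
  structure(list(beta = beta, lambda1 = lambda1, lambda2 = lambda2,
                 iterations = iters, converged = converged,
                 objective = objective(beta, sr, lambda1, lambda2),
                 response = sr$response, k = sr$k, P = sr$P,
                 cv_surface = NULL),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("fit_result for '%s': %d/%d non-zero coefficients, lambda = (%g, %g), objective %.6g%s\n",
              if (is.null(x$response)) "?" else x$response,
              sum(x$beta != 0), length(x$beta), x$lambda1, x$lambda2,
              x$objective, if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' Independent convex solver (verification oracle)
#'
#' Solves the identical objective by the alternating direction method of
#' multipliers on the generalized-lasso splitting `z = D beta`, with
#' soft-threshold updates for z.  Shares no code with [fit_lqa()] and is
#' intended for testing on small instances; a size guard rejects large
#' problems.
#'
#' @param sr A `stacked_regression`.
#' @param lambda1,lambda2 Non-negative penalties.
#' @param rho ADMM step size.
#' @param max_iterations,tolerance Stopping controls (primal/dual
#'   residual norms).
#' @return Coefficient vector beta.
#' @export
fit_oracle <- function(sr, lambda1, lambda2, rho = 1,
                       max_iterations = 20000L, tolerance = 1e-11) {
  n <- nrow(sr$X)
  p <- ncol(sr$X)
  if (n > 200L || p > 60L) {
    stopf("fit_oracle is a small-instance verification oracle (n <= 200, kP <= 60)")
  }
  D <- rbind(sr$D1, sr$D2)
  lam <- c(rep(lambda1, nrow(sr$D1)), rep(lambda2, nrow(sr$D2)))
  XtX <- crossprod(sr$X)
  XtY <- as.numeric(crossprod(sr$X, sr$Y))
  M <- 2 * XtX + rho * crossprod(D)
  R <- tryCatch(chol(M), error = function(e) NULL)
  if (is.null(R)) {
    stopf("oracle system is singular; use a full-column-rank instance")
  }
  soft <- function(v, kap) sign(v) * pmax(abs(v) - kap, 0)
  beta <- numeric(p)
  z <- numeric(nrow(D))
  u <- numeric(nrow(D))
  kap <- lam / rho
  for (it in seq_len(max_iterations)) {
    rhs <- 2 * XtY + rho * as.numeric(crossprod(D, z - u))
    beta <- backsolve(R, backsolve(R, rhs, transpose = TRUE))
    Db <- as.numeric(D %*% beta)
    z_old <- z
    z <- soft(Db + u, kap)
    u <- u + Db - z
    pri <- sqrt(sum((Db - z)^2))
    dua <- rho * sqrt(sum(as.numeric(crossprod(D, z - z_old))^2))
    if (pri < tolerance * (1 + sqrt(sum(Db^2))) &&
        dua < tolerance * (1 + sqrt(sum(beta^2)))) break
  }
  as.numeric(beta)
}

#' Cross-validated penalty selection and final fit
#'
#' Rows are partitioned into folds stratified by condition block, so
#' every training split contains rows from all k conditions.  For every
#' (lambda1, lambda2) pair on the grid the mean squared prediction error
#' on held-out rows is computed; the pair with minimum CV error wins,
#' with ties broken toward larger lambda1 + lambda2 (the sparser,
#' more fused model).  The final model is refit on all rows.
#'
#' @param sr A `stacked_regression`.
#' @param lambda1_grid,lambda2_grid Non-empty non-negative grids.
#' @param folds Number of folds (>= 2); every condition must contribute
#'   at least `folds` rows.
#' @param seed Integer seed for the fold assignment.
#' @param opts A `solver_options`.
#' @return A `fit_result` with the CV error surface in `$cv_surface`
#'   (matrix lambda1 x lambda2) and the fold assignment in `$folds`.
#' @export
cross_validate <- function(sr, lambda1_grid, lambda2_grid, folds = 10L,
                           seed = 1L, opts = solver_options()) {
  folds <- as.integer(folds)
  if (folds < 2L) stopf("folds must be >= 2")
  if (length(lambda1_grid) == 0L || length(lambda2_grid) == 0L) {
    stopf("lambda grids must be non-empty")
  }
  short <- sr$N < folds
  if (any(short)) {
    stopf("condition(s) %s have fewer rows than folds = %d; lower the number of folds so every fold samples every condition",
          paste(sr$condition_names[short], collapse = ", "), folds)
  }
  fold_id <- integer(length(sr$Y))
  with_seed(seed, {
    for (i in seq_len(sr$k)) {
      rows <- which(sr$condition_of_row == i)
      fold_id[rows] <- sample(rep_len(seq_len(folds), length(rows)))
    }
  })

  l1g <- as.numeric(lambda1_grid)
  l2g <- as.numeric(lambda2_grid)
  cv <- matrix(0, length(l1g), length(l2g),
               dimnames = list(paste0("l1=", l1g), paste0("l2=", l2g)))
  for (f in seq_len(folds)) {
    test <- fold_id == f
    sr_tr <- sr
    sr_tr$X <- sr$X[!test, , drop = FALSE]
    sr_tr$Y <- sr$Y[!test]
    sr_tr$condition_of_row <- sr$condition_of_row[!test]
    for (a in seq_along(l1g)) {
      for (b in seq_along(l2g)) {
        fit <- fit_lqa(sr_tr, l1g[a], l2g[b], opts)
        pred <- as.numeric(sr$X[test, , drop = FALSE] %*% fit$beta)
        cv[a, b] <- cv[a, b] + sum((sr$Y[test] - pred)^2)
      }
    }
  }
  cv <- cv / length(sr$Y)

  best <- which(cv == min(cv), arr.ind = TRUE)
  if (nrow(best) > 1L) {
    tot <- l1g[best[, 1L]] + l2g[best[, 2L]]
    best <- best[order(-tot, best[, 1L], best[, 2L]), , drop = FALSE]
  }
  l1 <- l1g[best[1L, 1L]]
  l2 <- l2g[best[1L, 2L]]
  fit <- fit_lqa(sr, l1, l2, opts)
  fit$cv_surface <- cv
  fit$folds <- fold_id
  fit
}
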