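# Assembly of the per-response stacked regression.
#
# The k condition data sets are combined into one block-diagonal design
# matrix X (rows = time points of all conditions, columns = k blocks of
# the P regressors), the response profiles are stacked into Y, and the
# penalty matrix D = [D1; D2] is built: D1 is diagonal with the
# differential-behavior weights (the weighted LASSO penalty) and every
# row of D2 encodes one consecutive-pair coefficient difference
# beta^i_j - beta^{i+1}_j (the fusion penalty).

#' Assemble the stacked regression for one response gene
#'
#' Within each condition block the regressor columns are centered and
#' scaled to unit standard deviation over that condition's time points
#' and the response is centered (no intercept); coefficients are
#' therefore on the standardized scale.  A regressor that is constant
#' within a condition becomes a zero column.  If the response is itself
#' a regulator its own column is removed from every block.
#'
#' @param study A `multi_condition_study`.
#' @param probabilities List of `de_prob_matrix`, one per condition, in
#'   study order.
#' @param response_id Response gene ID.
#' @param regulator_ids Regressors; defaults to the study's regulators.
#' @param standardize Center/scale columns per condition block.
#' @return A `stacked_regression`: list with `X` ((sum N^i) x (k P')),
#'   `Y`, `D1`, `D2`, `k`, `P`, `regulators`, `response`,
#'   `condition_of_row`, `condition_names`, `standardize`.
#' @export
assemble <- function(study, probabilities, response_id,
                     regulator_ids = NULL, standardize = TRUE) {
  if (is.null(regulator_ids)) regulator_ids <- study$regulator_ids
  regulator_ids <- sort(setdiff(regulator_ids, response_id))
  k <- study$k
  P <- length(regulator_ids)
  if (P < 1L) stopf("no regressors left after removing the response itself")
  if (!response_id %in% study$genes) stopf("unknown response gene '%s'", response_id)
  if (length(probabilities) != k) {
    stopf("need one probability matrix per condition (%d != %d)",
          length(probabilities), k)
  }

  Ns <- vapply(study$datasets, function(d) ncol(d$treatment), integer(1L))
  if (any(Ns == 0L)) stopf("a condition has zero time points")
  n_total <- sum(Ns)
  X <- matrix(0, n_total, k * P)
  Y <- numeric(n_total)
  w_all <- numeric(k * P)
  row_cond <- integer(n_total)
  row0 <- 0L
  for (i in seq_len(k)) {
    trt <- study$datasets[[i]]$treatment
    missing <- setdiff(c(response_id, regulator_ids), rownames(trt))
    if (length(missing) > 0L) {
      stopf("gene(s) missing from condition '%s': %s",
            study$condition_names[i], paste(missing, collapse = ", "))
    }
    Xi <- t(trt[regulator_ids, , drop = FALSE])     # N^i x P
    yi <- trt[response_id, ]
    if (standardize) {
      mu <- colMeans(Xi)
      sdv <- apply(Xi, 2L, stats::sd)
      sdv[!is.finite(sdv) | sdv < 1e-12] <- Inf     # constant column -> zeros
      Xi <- sweep(sweep(Xi, 2L, mu, `-`), 2L, sdv, `/`)
      yi <- yi - mean(yi)
    }
    rows <- row0 + seq_len(Ns[i])
    cols <- (i - 1L) * P + seq_len(P)
    X[rows, cols] <- Xi
    Y[rows] <- yi
    row_cond[rows] <- i
    w_all[cols] <- as.numeric(response_weights(probabilities[[i]],
                                               response_id, regulator_ids))
    row0 <- row0 + Ns[i]
  }

  D1 <- diag(w_all, nrow = k * P)
  D2 <- fusion_matrix(k, P)
  structure(list(X = X, Y = Y, D1 = D1, D2 = D2, k = k, P = P,
                 regulators = regulator_ids, response = response_id,
                 N = Ns, condition_of_row = row_cond,
                 condition_names = study$condition_names,
                 standardize = standardize),
            class = "stacked_regression")
}

# (k-1)P x kP matrix of consecutive-pair differences: one +1 and one -1
# per row, P columns apart.
fusion_matrix <- function(k, P) {
  if (k < 2L) return(matrix(0, 0L, k * P))
  D2 <- matrix(0, (k - 1L) * P, k * P)
  for (i in seq_len(k - 1L)) {
    for (j in seq_len(P)) {
      r <- (i - 1L) * P + j
      D2[r, (i - 1L) * P + j] <- 1
      D2[r, i * P + j] <- -1
    }
  }
  D2
}

#' @export
print.stacked_regression <- function(x, ...) {
  cat(sprintf("stacked_regression for response '%s': %d rows, k = %d, P = %d (%d fusion rows)\n",
              x$response, length(x$Y), x$k, x$P, nrow(x$D2)))
  invisible(x)
}

#' Split a stacked coefficient vector into per-condition blocks
#'
#' Coefficient (i-1)*P + j belongs to condition i, regressor j;
#' concatenating the returned blocks in order reproduces `beta`.
#'
#' @param beta Numeric vector of length k * P.
#' @param k Number of conditions.
#' @param P Number of regressors per block.
#' @return List of k numeric vectors of length P.
#' @export
blocks_of <- function(beta, k, P) {
  if (length(beta) != k * P) {
    stopf("length(beta) = %d but k * P = %d", length(beta), k * P)
  }
  lapply(seq_len(k), function(i) beta[(i - 1L) * P + seq_len(P)])
}
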