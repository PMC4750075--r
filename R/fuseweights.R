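# Differential-behavior penalty weights.
#
# The weight between a response gene Y and a regressor j in condition i
# is the mean absolute difference of their differential-expression
# probability profiles over the condition's time points:
#
#   w^i_{Y,j} = (1 / N^i) * sum_t | pr_{Y,t} - pr_{j,t} |
#
# A small weight means the two genes behave similarly under the
# perturbation (both responsive or both unaffected), so the edge is
# penalized less in the fused LASSO.  Division by N^i keeps weights in
# [0, 1] and comparable across conditions with different numbers of
# time points.

#' Penalty weights of one response against the regulators
#'
#' @param pr A `de_prob_matrix` for one condition.
#' @param response_id Response gene ID.
#' @param regulator_ids Regressor gene IDs.
#' @return A `response_weights` object: numeric vector in \[0, 1\] named
#'   by regulator, with attributes `response` and `condition`.  The
#'   self-entry (if the response is itself a regulator) is 0 by the
#'   definition and is removed from the regression downstream.
#' @export
response_weights <- function(pr, response_id, regulator_ids) {
  p <- pr$prob
  unknown <- setdiff(c(response_id, regulator_ids), rownames(p))
  if (length(unknown) > 0L) {
    stopf("gene ID(s) absent from probability matrix: %s",
          paste(unknown, collapse = ", "))
  }
  py <- p[response_id, ]
  w <- vapply(regulator_ids, function(j) mean(abs(py - p[j, ])), numeric(1L))
  structure(w, response = response_id, condition = pr$condition,
            class = "response_weights")
}

#' All-pairs weight matrix for one condition
#'
#' Symmetric with zeros along the diagonal; entry (a, b) equals
#' `response_weights` with response a and regressor b.
#'
#' @param pr A `de_prob_matrix`.
#' @return Square symmetric numeric matrix over all genes in `pr`.
#' @export
pairwise_weight_matrix <- function(pr) {
  p <- pr$prob
  g <- nrow(p)
  # mean |p_a. - p_b.| for all pairs; loop over time points keeps memory O(g^2)
  m <- matrix(0, g, g, dimnames = list(rownames(p), rownames(p)))
  for (t in seq_len(ncol(p))) {
    m <- m + abs(outer(p[, t], p[, t], `-`))
  }
  m / ncol(p)
}
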