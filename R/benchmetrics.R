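# Evaluation of inferred networks against a gold standard: ROC and
# precision-recall curves, AUROC, AUPR, TPR at a fixed FPR, the
# selector value, the OverallScore over several data sets and signed
# regulatory-type accuracies.
#
# Scoring convention: every ordered (regulator, target) pair of the
# universe is scoreable; pairs absent from the network score 0 and tie
# at the final threshold.  Ties are handled by grouping the threshold
# sweep at distinct scores, which makes the trapezoidal AUROC equal the
# Mann-Whitney probability (ties counted 1/2) that a random true edge
# outranks a random non-edge.

#' The scoreable pair universe
#'
#' All ordered regulator -> target pairs, self-pairs excluded.
#'
#' @param regulators,targets Character vectors of gene IDs.
#' @return Data frame with columns `regulator`, `target`.
#' @export
pair_universe <- function(regulators, targets) {
  u <- expand.grid(regulator = regulators, target = targets,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  u <- u[u$regulator != u$target, , drop = FALSE]
  rownames(u) <- NULL
  u
}

pair_key <- function(reg, tgt) paste(reg, tgt, sep = "\r")

#' ROC / PR evaluation of a network against a gold standard
#'
#' @param network A normalized `grn_network` (or any data frame with
#'   `regulator`, `target`, `weight`).
#' @param gold A `gold_standard`; every gold edge must lie inside the
#'   universe.
#' @param universe Data frame of scoreable pairs from [pair_universe()].
#' @param fpr_at FPR at which the TPR is reported (step-curve value at
#'   the largest achieved FPR <= `fpr_at`).
#' @return An `eval_report`: list with `roc` (FPR, TPR points), `pr`
#'   (recall, precision points), `auroc`, `aupr`, `tpr_at_fpr`,
#'   `fpr_at`, `n_gold`, `n_pairs`.
#' @export
roc_pr <- function(network, gold, universe, fpr_at = 0.03) {
  if (nrow(gold) == 0L) stopf("gold standard is empty")
  ukey <- pair_key(universe$regulator, universe$target)
  gkey <- pair_key(gold$regulator, gold$target)
  outside <- setdiff(gkey, ukey)
  if (length(outside) > 0L) {
    stopf("%d gold edge(s) outside the scoreable universe (first: %s)",
          length(outside), sub("\r", " -> ", outside[1L]))
  }
  score <- numeric(length(ukey))
  if (nrow(network) > 0L) {
    nkey <- pair_key(network$regulator, network$target)
    idx <- match(nkey, ukey)
    ok <- !is.na(idx)
    score[idx[ok]] <- network$weight[ok]
  }
  label <- ukey %in% gkey

  n_pos <- sum(label)
  n_neg <- sum(!label)

  # threshold sweep grouped at distinct scores, descending
  o <- order(-score)
  s <- score[o]
  l <- label[o]
  grp_last <- cumsum(rle(s)$lengths)
  tp <- cumsum(l)[grp_last]
  fp <- cumsum(!l)[grp_last]
  tpr <- c(0, tp / n_pos)
  fpr <- c(0, fp / n_neg)
  prec <- c(1, tp / (tp + fp))
  rec <- tpr

  auroc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  aupr <- sum(diff(rec) * utils::tail(prec, -1))

  below <- which(fpr <= fpr_at + 1e-12)
  tpr_at <- if (length(below) > 0L) tpr[max(below)] else 0

  structure(list(roc = data.frame(fpr = fpr, tpr = tpr),
                 pr = data.frame(recall = rec, precision = prec),
                 auroc = auroc, aupr = aupr,
                 tpr_at_fpr = tpr_at, fpr_at = fpr_at,
                 n_gold = n_pos, n_pairs = n_pos + n_neg),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("eval_report: AUROC %.4f, AUPR %.4f, TPR@FPR=%.3g %.4f (%d gold edges, %d pairs)\n",
              x$auroc, x$aupr, x$fpr_at, x$tpr_at_fpr, x$n_gold, x$n_pairs))
  invisible(x)
}

#' Selector value
#'
#' The normalized weight of the highest-ranked edge of the network that
#' is a gold-standard edge; 0 (with a warning) when no true positive is
#' present in the retained edge list.  Values near 1 mean true edges
#' receive top scores.
#'
#' @param network A normalized `grn_network`.
#' @param gold A non-empty `gold_standard`.
#' @return Scalar in \[0, 1\].
#' @export
selector_value <- function(network, gold) {
  if (nrow(gold) == 0L) stopf("gold standard is empty")
  if (nrow(network) == 0L) {
    warnf("empty network: selector value is 0")
    return(0)
  }
  hit <- pair_key(network$regulator, network$target) %in%
    pair_key(gold$regulator, gold$target)
  if (!any(hit)) {
    warnf("no true positive in the retained edge list: selector value is 0")
    return(0)
  }
  max(network$weight[hit])
}

#' OverallScore across data sets
#'
#' The AUROCscore is the geometric mean of the per-data-set AUROCs, the
#' AUPRscore the geometric mean of the AUPRs, and the OverallScore the
#' arithmetic mean of the two.
#'
#' @param auroc,aupr Numeric vectors of equal length with values in
#'   (0, 1\].
#' @return List with `auroc_score`, `aupr_score`, `overall`.
#' @export
overall_score <- function(auroc, aupr) {
  stopifnot(length(auroc) == length(aupr), length(auroc) > 0L)
  if (any(auroc <= 0) || any(aupr <= 0)) {
    stopf("geometric mean undefined for non-positive inputs")
  }
  gm <- function(x) exp(mean(log(x)))
  a <- gm(auroc)
  p <- gm(aupr)
  list(auroc_score = a, aupr_score = p, overall = (a + p) / 2)
}

#' Signed regulatory-type accuracy
#'
#' Fractions of gold activating (+) and repressing (-) edges that are
#' both predicted and carry the correct sign; the TP fraction of gold
#' edges predicted irrespective of sign; and the TN fraction of
#' universe non-edges that are (correctly) not predicted.
#'
#' @param network A `grn_network` with a `sign` column.
#' @param gold A `gold_standard` containing signed edges.
#' @param universe Scoreable pairs from [pair_universe()].
#' @return List with `plus_fraction`, `minus_fraction`, `tp`, `tn`.
#' @export
type_fractions <- function(network, gold, universe) {
  signed <- !is.na(gold$sign)
  if (!any(signed)) stopf("gold standard carries no signed edges")
  gkey <- pair_key(gold$regulator, gold$target)
  nkey <- pair_key(network$regulator, network$target)
  pred_sign <- network$sign[match(gkey, nkey)]     # NA if not predicted

  act <- signed & gold$sign > 0
  rep_ <- signed & gold$sign < 0
  plus_fraction <- if (any(act)) {
    sum(!is.na(pred_sign[act]) & pred_sign[act] > 0) / sum(act)
  } else NA_real_
  minus_fraction <- if (any(rep_)) {
    sum(!is.na(pred_sign[rep_]) & pred_sign[rep_] < 0) / sum(rep_)
  } else NA_real_

  tp <- mean(gkey %in% nkey)
  ukey <- pair_key(universe$regulator, universe$target)
  non_edges <- setdiff(ukey, gkey)
  tn <- if (length(non_edges) > 0L) mean(!non_edges %in% nkey) else NA_real_
  list(plus_fraction = plus_fraction, minus_fraction = minus_fraction,
       tp = tp, tn = tn)
}

#' Write an evaluation report as a one-metric-per-row TSV
#'
#' @param report An `eval_report` (optionally with extra scalar metrics
#'   appended as a named list via `extra`).
#' @param path Output path.
#' @param extra Optional named list of additional scalar metrics.
#' @export
write_eval_report <- function(report, path, extra = NULL) {
  metrics <- c(auroc = report$auroc, aupr = report$aupr,
               tpr_at_fpr = report$tpr_at_fpr, fpr_at = report$fpr_at,
               n_gold = report$n_gold, n_pairs = report$n_pairs)
  if (!is.null(extra)) metrics <- c(metrics, unlist(extra))
  writeLines(c("metric\tvalue",
               sprintf("%s\t%.10g", names(metrics), metrics)), path)
  invisible(path)
}
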