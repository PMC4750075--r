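# Network assembly: one fused regression per response gene, collection
# of the per-condition coefficient blocks into edges, consensus and
# normalization for ranking.

#' Fit the fused regression for one response gene
#'
#' Builds the penalty weights and stacked regression for the response
#' and runs cross-validated penalty selection.  The fold assignment is
#' seeded deterministically from the config seed and the response ID, so
#' results are identical regardless of the order in which responses are
#' processed.
#'
#' @param study A `multi_condition_study`.
#' @param probabilities List of `de_prob_matrix`, one per condition.
#' @param response_id Response gene ID.
#' @param config A `study_config`.
#' @param opts A `solver_options`.
#' @return A `fit_result` tagged with the response ID.
#' @export
infer_gene <- function(study, probabilities, response_id, config,
                       opts = solver_options()) {
  sr <- assemble(study, probabilities, response_id,
                 standardize = config$standardize)
  cross_validate(sr, config$lambda1_grid, config$lambda2_grid,
                 folds = config$cv_folds,
                 seed = derive_seed(config$rng_seed, response_id),
                 opts = opts)
}

#' Infer the full network
#'
#' Runs one fused regression per response gene (independently, so the
#' work parallelizes over forked workers without changing the result),
#' keeps every regulator-response pair with a non-zero coefficient in at
#' least one condition, forms the consensus coefficient and normalizes
#' edge weights to \[0, 1\].
#'
#' @param study A `multi_condition_study`.
#' @param probabilities List of `de_prob_matrix`; computed from the
#'   study when NULL.
#' @param config A `study_config`.
#' @param workers Number of forked workers (1 = serial).
#' @param opts A `solver_options`.
#' @return A `grn_network` (see [grn_network()]).
#' @export
infer_network <- function(study, probabilities = NULL, config = study_config(),
                          workers = 1L, opts = solver_options()) {
  if (is.null(probabilities)) {
    probabilities <- compute_probabilities(study, prior_p = config$de_prior_p)
  }
  responses <- study$response_ids
  if (length(responses) == 0L) stopf("study has no response genes")

  one <- function(rid) {
    tryCatch(infer_gene(study, probabilities, rid, config, opts),
             error = function(e) e)
  }
  fits <- if (workers > 1L) {
    parallel::mclapply(responses, one, mc.cores = workers)
  } else {
    lapply(responses, one)
  }
  failed <- vapply(fits, inherits, logical(1L), "condition")
  if (any(failed)) {
    warnf("%d response(s) failed and were skipped (first error: %s)",
          sum(failed), conditionMessage(fits[[which(failed)[1L]]]))
  }
  fits <- fits[!failed]
  responses <- responses[!failed]

  k <- study$k
  rows <- vector("list", length(fits))
  for (i in seq_along(fits)) {
    fit <- fits[[i]]
    regs <- sort(setdiff(study$regulator_ids, responses[i]))
    blocks <- blocks_of(fit$beta, k, length(regs))
    bm <- do.call(cbind, blocks)              # P' x k
    keep <- rowSums(bm != 0) > 0
    if (!any(keep)) next
    rows[[i]] <- data.frame(regulator = regs[keep],
                            target = responses[i],
                            bm[keep, , drop = FALSE],
                            stringsAsFactors = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, logical(1L))]
  beta_names <- paste0("beta_", study$condition_names)
  if (length(rows) == 0L) {
    edges <- data.frame(regulator = character(), target = character())
    for (nm in beta_names) edges[[nm]] <- numeric()
  } else {
    edges <- do.call(rbind, rows)
    colnames(edges)[2L + seq_len(k)] <- beta_names
  }
  net <- grn_network(edges, condition_names = study$condition_names,
                     consensus_mode = config$consensus_mode)
  normalize_edges(net, top_n = config$top_n_edges)
}

#' Construct a network object from an edge table
#'
#' @param edges Data frame with columns `regulator`, `target` and one
#'   `beta_<condition>` column per condition.
#' @param condition_names Condition labels (order matches the beta
#'   columns).
#' @param consensus_mode "max" (coefficient of largest magnitude across
#'   conditions, sign preserved) or "average" (arithmetic mean).
#' @return A `grn_network`: the edge data frame gains `consensus`,
#'   `sign` and (after [normalize_edges()]) `weight` columns.
#' @export
grn_network <- function(edges, condition_names,
                        consensus_mode = c("max", "average")) {
  consensus_mode <- match.arg(consensus_mode)
  beta_cols <- paste0("beta_", condition_names)
  stopifnot(all(c("regulator", "target", beta_cols) %in% colnames(edges)))
  if (nrow(edges) > 0L) {
    bm <- as.matrix(edges[, beta_cols, drop = FALSE])
    edges$consensus <- apply(bm, 1L, consensus_coefficient, mode = consensus_mode)
    edges$sign <- ifelse(edges$consensus >= 0, 1L, -1L)
  } else {
    edges$consensus <- numeric()
    edges$sign <- integer()
  }
  rownames(edges) <- NULL
  structure(edges,
            condition_names = condition_names,
            consensus_mode = consensus_mode,
            class = c("grn_network", "data.frame"))
}

#' Consensus of per-condition coefficients for one edge
#'
#' @param beta_blocks Numeric vector of the edge's k per-condition
#'   coefficients.
#' @param mode "max" or "average".
#' @return Scalar consensus coefficient.  For "max" the coefficient of
#'   largest absolute value is returned with its sign (first such block
#'   on ties).
#' @export
consensus_coefficient <- function(beta_blocks, mode = c("max", "average")) {
  mode <- match.arg(mode)
  if (length(beta_blocks) == 0L) stopf("empty coefficient vector")
  if (mode == "average") {
    mean(beta_blocks)
  } else {
    beta_blocks[which.max(abs(beta_blocks))]
  }
}

#' Normalize and rank network edges
#'
#' Normalized weight = |consensus| / max |consensus| over retained
#' edges, so the top edge has weight 1.  Edges are sorted by descending
#' weight (ties broken lexicographically by regulator then target for
#' reproducible output) and the top `top_n` are retained.  The signed
#' pre-normalization coefficients are preserved.
#'
#' @param network A `grn_network`.
#' @param top_n Number of edges to retain.
#' @return The normalized, sorted, truncated `grn_network`.
#' @export
normalize_edges <- function(network, top_n = 100000L) {
  if (nrow(network) == 0L) {
    warnf("empty network: nothing to normalize")
    network$weight <- numeric()
    return(network)
  }
  w <- abs(network$consensus) / max(abs(network$consensus))
  network$weight <- w
  o <- order(-w, network$regulator, network$target)
  network <- network[o, , drop = FALSE]
  rownames(network) <- NULL
  head_n <- min(as.integer(top_n), nrow(network))
  structure(network[seq_len(head_n), , drop = FALSE],
            condition_names = attr(network, "condition_names"),
            consensus_mode = attr(network, "consensus_mode"),
            class = class(network))
}

#' Write a network edge table as TSV
#'
#' Columns: regulator, target, per-condition coefficients, consensus,
#' normalized weight, sign.
#'
#' @param network A `grn_network`.
#' @param path Output path.
#' @export
write_network <- function(network, path) {
  df <- as.data.frame(network)
  utils::write.table(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a network edge table written by [write_network()]
#'
#' @param path Path to the TSV file.
#' @return A `grn_network`.
#' @export
read_network <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE,
                          colClasses = "character")
  beta_cols <- grep("^beta_", colnames(df), value = TRUE)
  for (nm in c(beta_cols, "consensus", "weight")) df[[nm]] <- as.numeric(df[[nm]])
  df$sign <- as.integer(df$sign)
  structure(df,
            condition_names = sub("^beta_", "", beta_cols),
            consensus_mode = NA_character_,
            class = c("grn_network", "data.frame"))
}
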