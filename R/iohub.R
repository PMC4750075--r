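# Readers and writers for the on-disk formats, run configuration and the
# command-line front end.
#
# All tables are tab-separated with a header row.  Expression tables carry
# gene IDs in the first column ("gene_id") and one column per sample; gene
# IDs are case-sensitive strings.

#' Read a tab-separated expression matrix
#'
#' First column = gene IDs, header row = sample labels, numeric body.
#' Rows are returned sorted by gene ID so downstream assembly is
#' independent of the input row order.
#'
#' @param path Path to a TSV file.
#' @return Numeric matrix with gene IDs as row names.
#' @export
read_expression_matrix <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character")
  if (ncol(tab) < 2L) stopf("expression table %s needs >= 2 columns", path)
  ids <- tab[[1L]]
  if (anyDuplicated(ids)) {
    stopf("duplicate gene ID(s) in %s: %s", path,
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  body <- as.matrix(tab[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(body), nrow = nrow(body),
                                 dimnames = list(ids, colnames(body))))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1L, ]
    stopf("non-numeric or missing cell in %s (gene %s, sample %s)",
          path, ids[bad[1L]], colnames(num)[bad[2L]])
  }
  num[order(rownames(num)), , drop = FALSE]
}

#' Write an expression-style matrix as TSV
#'
#' @param m Numeric matrix with gene row names.
#' @param path Output path.
#' @export
write_expression_matrix <- function(m, path) {
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Load one condition's treatment and control matrices
#'
#' @param treatment_path TSV of treatment expression (genes x time points).
#' @param control_path TSV of control expression (genes x replicates).
#' @param condition Optional condition label.
#' @return A `condition_dataset`: list with `treatment`, `control`,
#'   `condition`, `time_points`.
#' @export
read_condition_dataset <- function(treatment_path, control_path,
                                   condition = NULL) {
  trt <- read_expression_matrix(treatment_path)
  ctl <- read_expression_matrix(control_path)
  if (!identical(rownames(trt), rownames(ctl))) {
    stopf("gene sets of treatment and control differ (%s vs %s)",
          treatment_path, control_path)
  }
  condition_dataset(trt, ctl, condition = condition)
}

#' Construct a condition data set from in-memory matrices
#'
#' @param treatment Genes x time-points numeric matrix with row names.
#' @param control Genes x control-replicates numeric matrix, same genes.
#' @param condition Optional label.
#' @return A `condition_dataset` object.
#' @export
condition_dataset <- function(treatment, control, condition = NULL) {
  stopifnot(is.matrix(treatment), is.matrix(control))
  if (is.null(rownames(treatment)) || is.null(rownames(control))) {
    stopf("treatment and control matrices need gene row names")
  }
  if (anyNA(treatment) || anyNA(control)) {
    stopf("missing values in condition data set%s",
          if (is.null(condition)) "" else paste0(" '", condition, "'"))
  }
  o <- order(rownames(treatment))
  treatment <- treatment[o, , drop = FALSE]
  control <- control[rownames(treatment), , drop = FALSE]
  structure(list(treatment = treatment, control = control,
                 condition = condition,
                 time_points = colnames(treatment)),
            class = "condition_dataset")
}

#' @export
print.condition_dataset <- function(x, ...) {
  cat(sprintf("condition_dataset '%s': %d genes, %d time points, %d control replicates\n",
              if (is.null(x$condition)) "?" else x$condition,
              nrow(x$treatment), ncol(x$treatment), ncol(x$control)))
  invisible(x)
}

#' Write a condition data set to two TSV files
#'
#' @param cd A `condition_dataset`.
#' @param treatment_path,control_path Output paths.
#' @export
write_condition_dataset <- function(cd, treatment_path, control_path) {
  write_expression_matrix(cd$treatment, treatment_path)
  write_expression_matrix(cd$control, control_path)
  invisible(cd)
}

#' Assemble a multi-condition study
#'
#' Aligns the gene universes of all condition data sets (intersection
#' semantics: genes absent from some condition are dropped with a
#' warning) and validates the regulator list.  The order of the data
#' sets is fixed at this point; the fusion penalty couples consecutive
#' pairs in this order.
#'
#' @param datasets List of `condition_dataset` objects (length k >= 1).
#' @param regulator_ids Character vector of transcription-factor gene IDs.
#' @param response_ids Optional character vector of response gene IDs;
#'   defaults to all non-regulator genes, or to the regulators themselves
#'   when every gene is a regulator (TF-on-TF regression).
#' @param condition_names Optional labels, defaulting to the data sets'
#'   own labels or "cond1" ... "condk".
#' @return A `multi_condition_study`.
#' @export
multi_condition_study <- function(datasets, regulator_ids,
                                  response_ids = NULL,
                                  condition_names = NULL) {
  k <- length(datasets)
  if (k < 1L) stopf("need at least one condition data set")
  for (d in datasets) {
    if (!inherits(d, "condition_dataset")) {
      stopf("all elements of 'datasets' must be condition_dataset objects")
    }
  }
  if (is.null(condition_names)) {
    condition_names <- vapply(seq_len(k), function(i) {
      lab <- datasets[[i]]$condition
      if (is.null(lab)) paste0("cond", i) else lab
    }, character(1L))
  }
  if (anyDuplicated(condition_names)) stopf("condition names must be unique")

  gene_sets <- lapply(datasets, function(d) rownames(d$treatment))
  genes <- Reduce(intersect, gene_sets)
  if (length(genes) == 0L) stopf("condition data sets share no genes")
  n_drop <- length(unique(unlist(gene_sets))) - length(genes)
  if (n_drop > 0L) {
    warnf("%d gene(s) absent from some condition(s) dropped (intersection semantics)",
          n_drop)
  }
  genes <- sort(genes)
  datasets <- lapply(seq_len(k), function(i) {
    d <- datasets[[i]]
    condition_dataset(d$treatment[genes, , drop = FALSE],
                      d$control[genes, , drop = FALSE],
                      condition = condition_names[i])
  })

  regulator_ids <- unique(as.character(regulator_ids))
  missing_reg <- setdiff(regulator_ids, genes)
  if (length(missing_reg) > 0L) {
    stopf("regulator ID(s) not in the shared gene universe: %s",
          paste(missing_reg, collapse = ", "))
  }
  if (is.null(response_ids)) {
    response_ids <- setdiff(genes, regulator_ids)
    if (length(response_ids) == 0L) response_ids <- regulator_ids
  } else {
    response_ids <- unique(as.character(response_ids))
    missing_rsp <- setdiff(response_ids, genes)
    if (length(missing_rsp) > 0L) {
      stopf("response ID(s) not in the shared gene universe: %s",
            paste(missing_rsp, collapse = ", "))
    }
  }

  structure(list(datasets = datasets, genes = genes,
                 regulator_ids = regulator_ids,
                 response_ids = response_ids,
                 condition_names = condition_names,
                 k = k),
            class = "multi_condition_study")
}

#' @export
print.multi_condition_study <- function(x, ...) {
  cat(sprintf("multi_condition_study: k = %d conditions (%s), %d genes, %d regulators, %d responses\n",
              x$k, paste(x$condition_names, collapse = ", "),
              length(x$genes), length(x$regulator_ids),
              length(x$response_ids)))
  invisible(x)
}

#' Read a gold-standard edge list
#'
#' Two or three tab-separated columns: regulator, target, optional sign
#' token ("+", "-" or "?").  Duplicate (regulator, target) pairs are
#' collapsed with a warning when their signs agree and raise an error
#' when they conflict.
#'
#' @param path Path to the edge list (header optional; a first line
#'   starting with "regulator" is treated as a header).
#' @return A `gold_standard` data frame with columns `regulator`,
#'   `target`, `sign` (integer +1 / -1 / NA).
#' @export
read_gold_standard <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) > 0L && grepl("^regulator\\b", lines[1L], ignore.case = TRUE)) {
    lines <- lines[-1L]
  }
  if (length(lines) == 0L) {
    return(gold_standard(character(), character(), integer()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(parts)
  if (any(ncols < 2L)) stopf("edge list %s has a row with < 2 columns", path)
  reg <- vapply(parts, `[[`, character(1L), 1L)
  tgt <- vapply(parts, `[[`, character(1L), 2L)
  sgn_tok <- vapply(parts, function(p) if (length(p) >= 3L) p[[3L]] else "?",
                    character(1L))
  sgn <- ifelse(sgn_tok == "+", 1L, ifelse(sgn_tok == "-", -1L,
                ifelse(sgn_tok == "?", NA_integer_, -99L)))
  if (any(sgn == -99L, na.rm = TRUE)) {
    stopf("unparseable sign token(s) in %s: %s", path,
          paste(unique(sgn_tok[!sgn_tok %in% c("+", "-", "?")]), collapse = ", "))
  }
  gold_standard(reg, tgt, sgn)
}

#' Construct a gold standard from vectors
#'
#' @param regulator,target Character vectors of equal length.
#' @param sign Integer vector of +1 / -1 / NA (NA = unspecified type).
#' @return A `gold_standard` data frame.
#' @export
gold_standard <- function(regulator, target, sign = rep(NA_integer_, length(regulator))) {
  stopifnot(length(regulator) == length(target),
            length(sign) == length(regulator))
  df <- data.frame(regulator = as.character(regulator),
                   target = as.character(target),
                   sign = as.integer(sign),
                   stringsAsFactors = FALSE)
  key <- paste(df$regulator, df$target, sep = "\r")
  if (anyDuplicated(key)) {
    split_sign <- split(df$sign, key)
    conflict <- vapply(split_sign, function(s) {
      s <- unique(s[!is.na(s)])
      length(s) > 1L
    }, logical(1L))
    if (any(conflict)) {
      bad <- sub("\r", " -> ", names(split_sign)[conflict][1L])
      stopf("conflicting signs for duplicated edge %s", bad)
    }
    warnf("%d duplicated edge(s) collapsed", sum(duplicated(key)))
    keep_sign <- vapply(split_sign, function(s) {
      s <- unique(s[!is.na(s)])
      if (length(s) == 0L) NA_integer_ else s
    }, integer(1L))
    df <- df[!duplicated(key), , drop = FALSE]
    df$sign <- as.integer(keep_sign[paste(df$regulator, df$target, sep = "\r")])
    rownames(df) <- NULL
  }
  class(df) <- c("gold_standard", "data.frame")
  df
}

#' Write a gold standard as a TSV edge list
#'
#' @param gs A `gold_standard`.
#' @param path Output path.
#' @export
write_gold_standard <- function(gs, path) {
  tok <- ifelse(is.na(gs$sign), "?", ifelse(gs$sign > 0, "+", "-"))
  writeLines(c("regulator\ttarget\tsign",
               sprintf("%s\t%s\t%s", gs$regulator, gs$target, tok)), path)
  invisible(path)
}

#' Read a one-ID-per-line gene list
#'
#' @param path Path to a text file, one gene ID per line.
#' @return Character vector of unique IDs.
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  ids <- trimws(readLines(path))
  unique(ids[nzchar(ids)])
}

# ---------------------------------------------------------------------------
# Study configuration

#' Create a run configuration
#'
#' Defaults mirror the published protocol: penalty grids
#' lambda1 in \{0.05, 0.1, 0.5, 1, 1.5\} and lambda2 in
#' \{0.1, 0.5, 1, 1.5, 2\}, 10-fold cross-validation, consensus by the
#' maximum-magnitude per-condition coefficient, top 100,000 edges
#' retained, and a prior probability of differential expression of 0.01.
#'
#' @param condition_names Character vector of condition labels.
#' @param treatment_paths,control_paths Paths to the per-condition tables.
#' @param regulator_list_path Path to the TF gene list.
#' @param response_list_path Optional path to a response gene list.
#' @param lambda1_grid,lambda2_grid Non-negative penalty grids.
#' @param cv_folds Number of cross-validation folds (>= 2).
#' @param consensus_mode "max" or "average".
#' @param rng_seed Integer seed; all randomness flows from it.
#' @param top_n_edges Edges retained after ranking.
#' @param de_prior_p Prior probability that a gene is differentially
#'   expressed, in (0, 1).
#' @param standardize Standardize design columns per condition block.
#' @return A `study_config` list.
#' @export
study_config <- function(condition_names = character(),
                         treatment_paths = character(),
                         control_paths = character(),
                         regulator_list_path = NULL,
                         response_list_path = NULL,
                         lambda1_grid = c(0.05, 0.1, 0.5, 1, 1.5),
                         lambda2_grid = c(0.1, 0.5, 1, 1.5, 2),
                         cv_folds = 10L,
                         consensus_mode = c("max", "average"),
                         rng_seed = 1L,
                         top_n_edges = 100000L,
                         de_prior_p = 0.01,
                         standardize = TRUE) {
  consensus_mode <- match.arg(consensus_mode)
  lambda1_grid <- as.numeric(lambda1_grid)
  lambda2_grid <- as.numeric(lambda2_grid)
  if (length(lambda1_grid) == 0L || length(lambda2_grid) == 0L) {
    stopf("lambda grids must be non-empty")
  }
  if (any(lambda1_grid < 0) || any(lambda2_grid < 0)) {
    stopf("lambda grid values must be >= 0")
  }
  cv_folds <- as.integer(cv_folds)
  if (is.na(cv_folds) || cv_folds < 2L) stopf("cv_folds must be >= 2")
  if (anyDuplicated(condition_names)) stopf("condition names must be unique")
  if (!(de_prior_p > 0 && de_prior_p < 1)) stopf("de_prior_p must be in (0,1)")
  structure(list(condition_names = condition_names,
                 treatment_paths = treatment_paths,
                 control_paths = control_paths,
                 regulator_list_path = regulator_list_path,
                 response_list_path = response_list_path,
                 lambda1_grid = lambda1_grid,
                 lambda2_grid = lambda2_grid,
                 cv_folds = cv_folds,
                 consensus_mode = consensus_mode,
                 rng_seed = as.integer(rng_seed),
                 top_n_edges = as.integer(top_n_edges),
                 de_prior_p = de_prior_p,
                 standardize = isTRUE(standardize)),
            class = "study_config")
}

#' Read a flat key=value configuration file
#'
#' Lines of the form `key = value`; comma-separated values for list
#' fields; `#` starts a comment.  Unknown keys raise an error.  Relative
#' paths are resolved against the config file's directory.
#'
#' @param path Path to the config file.
#' @return A `study_config`.
#' @export
read_study_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([A-Za-z0-9_]+)\\s*=\\s*(.*)$", lines))
  bad <- lengths(kv) != 3L
  if (any(bad)) stopf("unparseable config line: '%s'", lines[bad][1L])
  keys <- vapply(kv, `[[`, character(1L), 2L)
  vals <- trimws(vapply(kv, `[[`, character(1L), 3L))
  names(vals) <- keys
  known <- c("condition_names", "treatment_paths", "control_paths",
             "regulator_list_path", "response_list_path",
             "lambda1_grid", "lambda2_grid", "cv_folds", "consensus_mode",
             "rng_seed", "top_n_edges", "de_prior_p", "standardize")
  unknown <- setdiff(keys, known)
  if (length(unknown) > 0L) {
    stopf("unknown config key(s): %s", paste(unknown, collapse = ", "))
  }
  base <- dirname(normalizePath(path))
  split_csv <- function(x) trimws(strsplit(x, ",", fixed = TRUE)[[1L]])
  resolve <- function(p) ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(base, p))
  args <- list()
  if ("condition_names" %in% keys) args$condition_names <- split_csv(vals["condition_names"])
  if ("treatment_paths" %in% keys) args$treatment_paths <- resolve(split_csv(vals["treatment_paths"]))
  if ("control_paths" %in% keys) args$control_paths <- resolve(split_csv(vals["control_paths"]))
  if ("regulator_list_path" %in% keys) args$regulator_list_path <- resolve(vals[["regulator_list_path"]])
  if ("response_list_path" %in% keys) args$response_list_path <- resolve(vals[["response_list_path"]])
  if ("lambda1_grid" %in% keys) args$lambda1_grid <- as.numeric(split_csv(vals["lambda1_grid"]))
  if ("lambda2_grid" %in% keys) args$lambda2_grid <- as.numeric(split_csv(vals["lambda2_grid"]))
  if ("cv_folds" %in% keys) args$cv_folds <- as.integer(vals[["cv_folds"]])
  if ("consensus_mode" %in% keys) args$consensus_mode <- vals[["consensus_mode"]]
  if ("rng_seed" %in% keys) args$rng_seed <- as.integer(vals[["rng_seed"]])
  if ("top_n_edges" %in% keys) args$top_n_edges <- as.integer(vals[["top_n_edges"]])
  if ("de_prior_p" %in% keys) args$de_prior_p <- as.numeric(vals[["de_prior_p"]])
  if ("standardize" %in% keys) args$standardize <- tolower(vals[["standardize"]]) %in% c("on", "true", "yes", "1")
  do.call(study_config, args)
}

#' Load the study described by a configuration
#'
#' @param config A `study_config` with condition paths and regulator list.
#' @return A `multi_condition_study`.
#' @export
read_study <- function(config) {
  k <- length(config$condition_names)
  if (k == 0L) stopf("config declares no conditions")
  if (length(config$treatment_paths) != k || length(config$control_paths) != k) {
    stopf("need one treatment and one control path per condition")
  }
  datasets <- lapply(seq_len(k), function(i) {
    read_condition_dataset(config$treatment_paths[i], config$control_paths[i],
                           condition = config$condition_names[i])
  })
  regulators <- read_gene_list(config$regulator_list_path)
  responses <- if (!is.null(config$response_list_path)) {
    read_gene_list(config$response_list_path)
  } else {
    NULL
  }
  multi_condition_study(datasets, regulators, response_ids = responses,
                        condition_names = config$condition_names)
}
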