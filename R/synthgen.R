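# Synthetic multi-condition studies with a planted signed TF -> target
# network, so the whole pipeline can be exercised and validated without
# external data.
#
# Data-generating process (log2-intensity scale, microarray-like):
# every gene has a baseline level; each TF follows a smooth random time
# course around its baseline in every condition, and TFs perturbed in a
# condition additionally receive a constant condition-specific shift.
# Target profiles are the planted linear combination of the *observed*
# TF treatment profiles (deviations from TF baselines) plus Gaussian
# noise, matching the linear model assumed by the regression.  Controls
# are baseline plus replicate noise.  The shift drives the
# differential-expression contrast (and hence the penalty weights);
# the smooth course provides the within-condition variation that the
# regression exploits.

#' Plant a random signed regulatory truth
#'
#' @param P_tf Number of transcription factors.
#' @param n_targets Number of (non-TF) target genes.
#' @param edges_per_target Distinct TF regulators per target
#'   (<= `P_tf`).
#' @param seed Integer seed.
#' @param effect_range Magnitude range for edge effects; signs are +/-
#'   with equal probability.
#' @param perturbed_fraction Fraction of TFs perturbed per condition
#'   (used by [simulate_study()]).
#' @param k Number of conditions for which perturbation sets are drawn.
#' @return A `planted_truth`: list with `tf_ids`, `target_ids`, `edges`
#'   (data frame regulator/target/effect), `perturbed` (list of k TF-ID
#'   vectors), `shift` (named per-condition shift sizes for perturbed
#'   TFs).
#' @export
simulate_truth <- function(P_tf = 10L, n_targets = 30L,
                           edges_per_target = 2L, seed = 1L,
                           effect_range = c(0.5, 2), k = 3L,
                           perturbed_fraction = 0.4) {
  if (edges_per_target > P_tf) {
    stopf("edges_per_target (%d) cannot exceed P_tf (%d)", edges_per_target, P_tf)
  }
  tf_ids <- sprintf("TF%02d", seq_len(P_tf))
  target_ids <- sprintf("G%03d", seq_len(n_targets))
  with_seed(seed, {
    edges <- if (edges_per_target > 0L) {
      do.call(rbind, lapply(target_ids, function(tg) {
        regs <- sample(tf_ids, edges_per_target)
        eff <- sample(c(-1, 1), edges_per_target, replace = TRUE) *
          stats::runif(edges_per_target, effect_range[1L], effect_range[2L])
        data.frame(regulator = regs, target = tg, effect = eff,
                   stringsAsFactors = FALSE)
      }))
    } else {
      data.frame(regulator = character(), target = character(),
                 effect = numeric())
    }
    n_pert <- max(1L, round(perturbed_fraction * P_tf))
    perturbed <- lapply(seq_len(k), function(i) sort(sample(tf_ids, n_pert)))
    shifts <- lapply(seq_len(k), function(i) {
      s <- sample(c(-1, 1), n_pert, replace = TRUE) * stats::runif(n_pert, 2, 4)
      names(s) <- perturbed[[i]]
      s
    })
    structure(list(tf_ids = tf_ids, target_ids = target_ids,
                   edges = edges, perturbed = perturbed, shift = shifts,
                   k = k, seed = as.integer(seed)),
              class = "planted_truth")
  })
}

#' The planted truth as a signed gold standard
#'
#' @param truth A `planted_truth`.
#' @return A `gold_standard` with signs from the planted effects.
#' @export
truth_gold_standard <- function(truth) {
  gold_standard(truth$edges$regulator, truth$edges$target,
                ifelse(truth$edges$effect >= 0, 1L, -1L))
}

# smooth random course of length N: two random Fourier modes, unit-ish
# amplitude
smooth_course <- function(N, amplitude = 1) {
  tt <- seq(0, 1, length.out = N)
  a <- stats::rnorm(2, 0, amplitude)
  ph <- stats::runif(2, 0, 2 * pi)
  a[1L] * sin(2 * pi * tt + ph[1L]) + a[2L] * sin(4 * pi * tt + ph[2L])
}

#' Simulate a multi-condition study from a planted truth
#'
#' @param truth A `planted_truth`.
#' @param k Number of conditions (must not exceed the number of
#'   perturbation sets drawn in the truth).
#' @param N Integer vector of time points per condition (length k).
#' @param noise_sd Gaussian noise standard deviation (log2 scale).
#' @param n_control Control replicates per condition.
#' @param seed Integer seed.
#' @return A `multi_condition_study` with the TFs as regulators and the
#'   targets as responses.
#' @export
simulate_study <- function(truth, k = 3L, N = rep(8L, k), noise_sd = 0.3,
                           n_control = 4L, seed = 1L) {
  if (k < 1L) stopf("k must be >= 1")
  if (length(N) != k) stopf("length(N) must equal k")
  if (k > truth$k) {
    stopf("truth only provides perturbation sets for %d condition(s)", truth$k)
  }
  tf <- truth$tf_ids
  tg <- truth$target_ids
  genes <- c(tf, tg)
  with_seed(seed, {
    baseline <- stats::rnorm(length(genes), mean = 7, sd = 1)
    names(baseline) <- genes
    datasets <- vector("list", k)
    for (i in seq_len(k)) {
      Ni <- N[i]
      # TF signal: smooth course (+ shift when perturbed in this condition)
      sig <- matrix(0, length(tf), Ni, dimnames = list(tf, NULL))
      for (j in tf) {
        sig[j, ] <- smooth_course(Ni)
        if (j %in% truth$perturbed[[i]]) {
          sig[j, ] <- sig[j, ] + truth$shift[[i]][[j]]
        }
      }
      tf_obs <- baseline[tf] + sig +
        matrix(stats::rnorm(length(tf) * Ni, 0, noise_sd), length(tf), Ni)
      # targets: planted linear combination of observed TF deviations
      tf_dev <- tf_obs - baseline[tf]
      tg_mat <- matrix(rep(baseline[tg], Ni), length(tg), Ni,
                       dimnames = list(tg, NULL))
      for (e in seq_len(nrow(truth$edges))) {
        r <- truth$edges$regulator[e]
        g <- truth$edges$target[e]
        tg_mat[g, ] <- tg_mat[g, ] + truth$edges$effect[e] * tf_dev[r, ]
      }
      tg_mat <- tg_mat +
        matrix(stats::rnorm(length(tg) * Ni, 0, noise_sd), length(tg), Ni)
      treatment <- rbind(tf_obs, tg_mat)
      colnames(treatment) <- paste0("t", seq_len(Ni))
      control <- matrix(rep(baseline, n_control), length(genes), n_control,
                        dimnames = list(genes, paste0("ctl", seq_len(n_control)))) +
        matrix(stats::rnorm(length(genes) * n_control, 0, noise_sd),
               length(genes), n_control)
      datasets[[i]] <- condition_dataset(treatment, control,
                                         condition = paste0("cond", i))
    }
    multi_condition_study(datasets, regulator_ids = tf, response_ids = tg)
  })
}

#' Write a simulated study to disk in the package's TSV formats
#'
#' Emits per-condition treatment/control tables, the regulator list,
#' the response list, the planted gold standard and a ready-to-run
#' configuration file.
#'
#' @param study A `multi_condition_study`.
#' @param truth The `planted_truth` it was generated from (for the gold
#'   standard), or NULL to skip it.
#' @param dir Output directory (created if needed).
#' @param config Optional `study_config` whose solver settings are
#'   copied into the emitted config file.
#' @return The path of the written config file, invisibly.
#' @export
write_study <- function(study, truth = NULL, dir, config = study_config()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tp <- file.path(dir, sprintf("%s_treatment.tsv", study$condition_names))
  cp <- file.path(dir, sprintf("%s_control.tsv", study$condition_names))
  for (i in seq_len(study$k)) {
    write_condition_dataset(study$datasets[[i]], tp[i], cp[i])
  }
  writeLines(study$regulator_ids, file.path(dir, "regulators.txt"))
  writeLines(study$response_ids, file.path(dir, "responses.txt"))
  if (!is.null(truth)) {
    write_gold_standard(truth_gold_standard(truth), file.path(dir, "gold_standard.tsv"))
  }
  cfg_path <- file.path(dir, "study.cfg")
  writeLines(c(
    sprintf("condition_names = %s", paste(study$condition_names, collapse = ",")),
    sprintf("treatment_paths = %s", paste(basename(tp), collapse = ",")),
    sprintf("control_paths = %s", paste(basename(cp), collapse = ",")),
    "regulator_list_path = regulators.txt",
    "response_list_path = responses.txt",
    sprintf("lambda1_grid = %s", paste(config$lambda1_grid, collapse = ",")),
    sprintf("lambda2_grid = %s", paste(config$lambda2_grid, collapse = ",")),
    sprintf("cv_folds = %d", config$cv_folds),
    sprintf("consensus_mode = %s", config$consensus_mode),
    sprintf("rng_seed = %d", config$rng_seed),
    sprintf("top_n_edges = %d", config$top_n_edges),
    sprintf("de_prior_p = %g", config$de_prior_p),
    sprintf("standardize = %s", if (config$standardize) "on" else "off")
  ), cfg_path)
  invisible(cfg_path)
}
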