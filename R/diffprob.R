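# Empirical-Bayes differential-expression probabilities.
#
# For each condition the treatment profile at every time point is
# contrasted against the mean of the control replicates.  Gene-wise
# residual variances (from the control replicates) are shrunk toward a
# common prior by the standard hierarchical model for microarray
# variances: s_g^2 | sigma_g^2 ~ sigma_g^2 * chisq_d / d with
# sigma_g^2 following a scaled inverse chi-square prior (d0, s0^2).
# The moderated t statistic uses the posterior variance, and the
# B statistic is the log posterior odds of differential expression under
# a two-component normal mixture on the true contrast.

#' Fit the variance-prior hyperparameters (d0, s0^2)
#'
#' Moment matching on log variances: with z = log(s^2),
#' E z = log(sigma^2) + digamma(d/2) - log(d/2) and
#' Var z = trigamma(d/2), so the excess spread of z over trigamma(d/2)
#' identifies the prior degrees of freedom d0 via
#' trigamma(d0/2) = Var(e), e = z - digamma(d/2) + log(d/2).
#' When the observed spread does not exceed trigamma(d/2) the variances
#' are deemed homogeneous and d0 = Inf.
#'
#' @param s2 Gene-wise sample variances (positive).
#' @param df Their degrees of freedom (scalar or vector).
#' @return List with `df_prior` (d0, possibly Inf) and `var_prior` (s0^2).
#' @export
fit_variance_prior <- function(s2, df) {
  df <- rep_len(df, length(s2))
  ok <- is.finite(s2) & s2 > 0
  if (!any(ok)) stopf("all gene variances are zero or missing; cannot fit prior")
  if (sum(ok) < length(s2)) {
    warnf("%d gene(s) with non-positive variance excluded from prior fit",
          sum(!ok))
  }
  z <- log(s2[ok])
  dfo <- df[ok]
  e <- z - digamma(dfo / 2) + log(dfo / 2)
  emean <- mean(e)
  n <- length(e)
  evar <- sum((e - emean)^2) / (n - 1) - mean(trigamma(dfo / 2))
  if (is.na(evar) || evar <= 0) {
    return(list(df_prior = Inf, var_prior = exp(emean)))
  }
  d0 <- 2 * trigamma_inverse(evar)
  s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  list(df_prior = d0, var_prior = s02)
}

# Solve trigamma(y) = x for y > 0 by Newton iteration on 1/trigamma,
# which is nearly linear in y.
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2L)
    y <- y + dif
    if (abs(dif / y) < 1e-10) break
  }
  y
}

#' Log posterior odds of differential expression (B statistic)
#'
#' Evaluates the log odds that the true contrast is non-zero, given a
#' moderated t statistic with `df_total` degrees of freedom, an
#' unscaled-variance ratio `r = (u^2 + v0) / u^2` (u = unscaled standard
#' error of the contrast, v0 = unscaled prior variance of a true
#' effect), and a prior probability `prior_p` of differential
#' expression.
#'
#' @param tstat Moderated t statistic(s).
#' @param df_total Total degrees of freedom (may be Inf).
#' @param r Variance inflation ratio, > 1.
#' @param prior_p Prior probability of differential expression in (0, 1).
#' @return B statistic(s), same shape as `tstat`.
#' @export
b_statistic <- function(tstat, df_total, r, prior_p) {
  t2 <- tstat^2
  kernel <- if (is.infinite(df_total)) {
    t2 * (1 - 1 / r) / 2
  } else {
    (1 + df_total) / 2 * log((t2 + df_total) / (t2 / r + df_total))
  }
  log(prior_p / (1 - prior_p)) - log(r) / 2 + kernel
}

#' Convert a B statistic to a probability
#'
#' `exp(B) / (1 + exp(B))`, evaluated overflow-safely.
#'
#' @param B Log-odds value(s); must be finite.
#' @return Probability in (0, 1), strictly increasing in B.
#' @export
b_to_probability <- function(B) {
  stats::plogis(B)
}

#' Moderated statistics for one condition
#'
#' @param dataset A `condition_dataset` whose control matrix has at
#'   least two replicate columns.
#' @param prior_p Prior probability of differential expression.
#' @param hyper Optional list overriding fitted hyperparameters:
#'   `df_prior`, `var_prior`, `v0` (unscaled prior effect variance).
#' @return A `moderated_stats` list: `contrast` (genes x time points),
#'   `s2` and `df` (gene variances), `df_prior`, `var_prior`, `s2_post`,
#'   `stdev_unscaled`, `v0`, `t` (moderated t), `B`, `prob`.
#' @export
moderated_stats <- function(dataset, prior_p = 0.01, hyper = NULL) {
  ctl <- dataset$control
  trt <- dataset$treatment
  m <- ncol(ctl)
  if (m < 2L) {
    stopf("condition '%s' has %d control column(s); >= 2 replicates are required to estimate variances (use supply_probabilities() for externally computed probabilities)",
          if (is.null(dataset$condition)) "?" else dataset$condition, m)
  }
  s2 <- row_vars(ctl)
  d <- m - 1
  contrast <- trt - rowMeans(ctl)

  fit <- if (is.null(hyper) || is.null(hyper$df_prior) || is.null(hyper$var_prior)) {
    fit_variance_prior(s2, d)
  } else {
    list(df_prior = hyper$df_prior, var_prior = hyper$var_prior)
  }
  d0 <- fit$df_prior
  s02 <- fit$var_prior
  s2_post <- if (is.infinite(d0)) {
    rep(s02, length(s2))
  } else {
    (d0 * s02 + d * s2) / (d0 + d)
  }
  # a single treatment observation minus the mean of m controls:
  # Var = sigma^2 * (1 + 1/m)
  u <- sqrt(1 + 1 / m)
  df_total <- d0 + d
  tstat <- contrast / (sqrt(s2_post) * u)

  v0 <- if (!is.null(hyper) && !is.null(hyper$v0)) {
    hyper$v0
  } else {
    estimate_effect_prior(tstat, df_total, u, prior_p)
  }
  r <- (u^2 + v0) / u^2
  B <- b_statistic(tstat, df_total, r, prior_p)
  structure(list(contrast = contrast, s2 = s2, df = d,
                 df_prior = d0, var_prior = s02, s2_post = s2_post,
                 stdev_unscaled = u, v0 = v0, df_total = df_total,
                 t = tstat, B = B, prob = b_to_probability(B),
                 prior_p = prior_p,
                 condition = dataset$condition),
            class = "moderated_stats")
}

# Estimate the unscaled prior variance v0 of true effects from the upper
# tail of the moderated t statistics: the top ceiling(prior_p/2 * n)
# |t| values are matched against the t quantiles they would occupy if
# they came from the inflated (DE) component, giving per-statistic
# estimates v0 = u^2 * ((t / t_target)^2 - 1) that are averaged after
# flooring at zero.  Falls back to a fixed multiple of the contrast
# variance (v0 = 9 u^2, i.e. typical true effects of three standard
# errors) when the tail is empty or carries no excess spread.
estimate_effect_prior <- function(tstat, df_total, u, prior_p) {
  fallback <- 9 * u^2
  tv <- abs(as.numeric(tstat))
  tv <- tv[is.finite(tv)]
  n <- length(tv)
  ntarget <- ceiling(prior_p / 2 * n)
  if (ntarget < 1L || n < 2L) return(fallback)
  tv <- sort(tv, decreasing = TRUE)[seq_len(ntarget)]
  p_tail <- (seq_len(ntarget) - 0.5) / n      # two-sided empirical tail prob
  q <- pmin(p_tail / prior_p, 1 - 1e-9)       # position within the DE component
  ttarget <- stats::qt(q / 2, df = df_total, lower.tail = FALSE)
  v0 <- u^2 * pmax((tv / ttarget)^2 - 1, 0)
  v0 <- mean(v0)
  if (!is.finite(v0) || v0 <= 0) fallback else v0
}

#' Differential-expression probability matrices for a study
#'
#' One genes x time-points matrix of probabilities per condition,
#' aligned with the study's gene universe.
#'
#' @param study A `multi_condition_study`.
#' @param prior_p Prior probability of differential expression.
#' @return List of `de_prob_matrix` objects, one per condition.
#' @export
compute_probabilities <- function(study, prior_p = 0.01) {
  lapply(study$datasets, function(d) {
    ms <- moderated_stats(d, prior_p = prior_p)
    de_prob_matrix(ms$prob, condition = d$condition)
  })
}

#' Construct a probability matrix object
#'
#' @param prob Genes x time-points matrix with entries in \[0, 1\] and
#'   gene row names.
#' @param condition Optional condition label.
#' @return A `de_prob_matrix`.
#' @export
de_prob_matrix <- function(prob, condition = NULL) {
  stopifnot(is.matrix(prob))
  if (is.null(rownames(prob))) stopf("probability matrix needs gene row names")
  if (anyNA(prob) || any(prob < 0) || any(prob > 1)) {
    stopf("probabilities must lie in [0, 1]")
  }
  structure(list(prob = prob, condition = condition), class = "de_prob_matrix")
}

#' Read an externally computed probability matrix
#'
#' Escape hatch for probabilities produced by an external
#' differential-expression pipeline; the file uses the expression-table
#' layout and all values must lie in \[0, 1\].
#'
#' @param path Path to the TSV file.
#' @param condition Optional condition label.
#' @return A `de_prob_matrix`.
#' @export
supply_probabilities <- function(path, condition = NULL) {
  m <- read_expression_matrix(path)
  if (any(m < 0) || any(m > 1)) {
    bad <- m[m < 0 | m > 1][1L]
    stopf("probability out of range in %s: %g", path, bad)
  }
  de_prob_matrix(m, condition = condition)
}

#' Write a probability matrix as TSV
#'
#' @param pr A `de_prob_matrix`.
#' @param path Output path.
#' @export
write_probabilities <- function(pr, path) {
  write_expression_matrix(pr$prob, path)
}
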