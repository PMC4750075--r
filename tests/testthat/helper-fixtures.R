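# Shared fixture builders.  Everything is generated in code at test
# time; no binary fixtures.

# Random stacked regression instance with block-diagonal design, random
# penalty weights and condition-stratified rows.  Built directly (not
# through assemble()) so solver tests do not depend on the stacker.
random_sr <- function(n, k, P, seed, weights = NULL) {
  set.seed(seed)
  X <- matrix(0, n, k * P)
  Y <- numeric(n)
  cond <- integer(n)
  per <- n %/% k
  Ns <- rep(per, k)
  Ns[k] <- n - per * (k - 1)
  row0 <- 0
  for (i in seq_len(k)) {
    rows <- row0 + seq_len(Ns[i])
    cols <- (i - 1) * P + seq_len(P)
    X[rows, cols] <- matrix(rnorm(Ns[i] * P), Ns[i], P)
    Y[rows] <- rnorm(Ns[i])
    cond[rows] <- i
    row0 <- row0 + Ns[i]
  }
  if (is.null(weights)) weights <- runif(k * P)
  structure(list(X = X, Y = Y, D1 = diag(weights, k * P),
                 D2 = fusegrn:::fusion_matrix(k, P),
                 k = k, P = P, N = Ns, condition_of_row = cond,
                 condition_names = paste0("c", seq_len(k)),
                 response = "resp", regulators = paste0("g", seq_len(P)),
                 standardize = FALSE),
            class = "stacked_regression")
}

# Small in-memory condition data set with named genes
toy_dataset <- function(genes = c("A", "B", "C"), N = 4, n_ctl = 3,
                        seed = 1, condition = "toy") {
  set.seed(seed)
  trt <- matrix(rnorm(length(genes) * N, 7, 1), length(genes), N,
                dimnames = list(genes, paste0("t", seq_len(N))))
  ctl <- matrix(rnorm(length(genes) * n_ctl, 7, 1), length(genes), n_ctl,
                dimnames = list(genes, paste0("c", seq_len(n_ctl))))
  condition_dataset(trt, ctl, condition = condition)
}

# Probability matrix with given values
toy_probs <- function(m, condition = "toy") {
  de_prob_matrix(m, condition = condition)
}

# Brute-force Mann-Whitney AUROC: probability that a random positive
# outranks a random negative, ties counting 1/2.
brute_force_auroc <- function(score, label) {
  pos <- score[label]
  neg <- score[!label]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# Full small-network inference run used by recovery tests
run_synthetic_pipeline <- function(seed, cv_folds = 4L, workers = 1L,
                                   P_tf = 10L, n_targets = 30L) {
  truth <- simulate_truth(P_tf = P_tf, n_targets = n_targets, seed = seed)
  study <- simulate_study(truth, seed = seed + 1000L)
  probs <- compute_probabilities(study)
  cfg <- study_config(rng_seed = seed, cv_folds = cv_folds)
  net <- infer_network(study, probs, cfg, workers = workers)
  list(truth = truth, study = study, net = net,
       gold = truth_gold_standard(truth),
       universe = pair_universe(study$regulator_ids, study$response_ids))
}
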