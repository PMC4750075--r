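mk_net <- function(reg, tgt, weight, sign = rep(1L, length(reg))) {
  structure(data.frame(regulator = reg, target = tgt, weight = weight,
                       sign = as.integer(sign), stringsAsFactors = FALSE),
            class = c("grn_network", "data.frame"))
}

test_that("perfect and degenerate rankings give the expected AUROC", {
  uni <- pair_universe(c("T1", "T2"), c("g1", "g2"))
  gold <- gold_standard(c("T1", "T2"), c("g1", "g2"))
  net <- mk_net(c("T1", "T2", "T1", "T2"), c("g1", "g2", "g2", "g1"),
                c(1, 0.9, 0.1, 0.05))
  rep <- roc_pr(net, gold, uni)
  expect_equal(rep$auroc, 1)
  expect_equal(rep$aupr, 1)

  # empty network: every pair ties at score 0
  empty <- mk_net(character(), character(), numeric())
  rep0 <- roc_pr(empty, gold, uni)
  expect_equal(rep0$auroc, 0.5)
  expect_equal(rep0$tpr_at_fpr, 0)
  expect_true(all(rep0$roc$tpr[rep0$roc$fpr <= 0.999] %in% c(0)))

  expect_error(roc_pr(net, gold_standard(character(), character()), uni),
               "empty")
  expect_error(roc_pr(net, gold_standard("T9", "g1"), uni), "outside")
})

test_that("AUROC equals the brute-force rank statistic on toy universes", {
  set.seed(14)
  for (rep_i in 1:20) {
    n_reg <- sample(2:8, 1)
    n_tgt <- sample(2:8, 1)
    regs <- sprintf("T%d", seq_len(n_reg))
    tgts <- sprintf("g%d", seq_len(n_tgt))
    uni <- pair_universe(regs, tgts)
    n_gold <- sample(1:(nrow(uni) - 1), 1)
    gidx <- sample(nrow(uni), n_gold)
    gold <- gold_standard(uni$regulator[gidx], uni$target[gidx])
    # random scores with deliberate ties, some pairs unscored
    nidx <- sample(nrow(uni), sample(0:nrow(uni), 1))
    net <- mk_net(uni$regulator[nidx], uni$target[nidx],
                  sample(seq(0, 1, 0.25), length(nidx), replace = TRUE))
    er <- roc_pr(net, gold, uni)
    score <- numeric(nrow(uni))
    score[nidx] <- net$weight
    label <- seq_len(nrow(uni)) %in% gidx
    if (all(label) || !any(label)) next
    expect_equal(er$auroc, brute_force_auroc(score, label), tolerance = 1e-12)
  }
})

test_that("AUROC and AUPR agree with pROC on an untied toy ranking", {
  skip_if_not_installed("pROC")
  set.seed(33)
  uni <- pair_universe(sprintf("T%d", 1:5), sprintf("g%d", 1:6))
  gidx <- sample(nrow(uni), 8)
  gold <- gold_standard(uni$regulator[gidx], uni$target[gidx])
  w <- runif(nrow(uni), 0.01, 1)
  net <- mk_net(uni$regulator, uni$target, w)
  er <- roc_pr(net, gold, uni)
  label <- as.integer(seq_len(nrow(uni)) %in% gidx)
  proc_auc <- as.numeric(pROC::auc(pROC::roc(label, w, quiet = TRUE,
                                             direction = "<")))
  expect_equal(er$auroc, proc_auc, tolerance = 1e-10)
})

test_that("TPR at a fixed FPR follows the step-curve convention", {
  uni <- pair_universe(sprintf("T%d", 1:10), sprintf("g%d", 1:11))
  gold <- gold_standard("T1", "g1")
  # the single gold edge is top-ranked: TPR jumps to 1 at the first step
  net <- mk_net(c("T1", "T2"), c("g1", "g2"), c(1, 0.5))
  er <- roc_pr(net, gold, uni, fpr_at = 0.03)
  expect_equal(er$tpr_at_fpr, 1)
  # gold edge ranked second: at FPR <= 0.03 only the first (false) step
  # has occurred, and 1/109 non-edges < 0.03 gives TPR still 1 there
  net2 <- mk_net(c("T2", "T1"), c("g2", "g1"), c(1, 0.5))
  er2 <- roc_pr(net2, gold, uni, fpr_at = 0.03)
  expect_equal(er2$tpr_at_fpr, 1)
  er3 <- roc_pr(net2, gold, uni, fpr_at = 0.001)
  expect_equal(er3$tpr_at_fpr, 0)
})

test_that("selector value picks the highest-ranked true positive's weight", {
  gold <- gold_standard(c("T1", "T2"), c("g1", "g2"))
  top_hit <- mk_net(c("T1", "T3"), c("g1", "g3"), c(1, 0.8))
  expect_equal(selector_value(top_hit, gold), 1)

  third <- mk_net(c("T3", "T4", "T1", "T2"), c("g3", "g4", "g1", "g2"),
                  c(1, 0.9, 0.7, 0.2))
  expect_equal(selector_value(third, gold), 0.7)
  # definitional maximality: >= any lower-ranked true positive's weight
  expect_gte(selector_value(third, gold), 0.2)

  miss <- mk_net("T3", "g3", 1)
  expect_warning(sv <- selector_value(miss, gold), "no true positive")
  expect_equal(sv, 0)
})

test_that("the OverallScore averages the two geometric means", {
  # constant inputs reduce to the plain average
  expect_equal(overall_score(rep(0.6, 4), rep(0.01, 4))$overall,
               (0.6 + 0.01) / 2)
  # permutation of the data-set list leaves the score unchanged
  a <- c(0.642, 0.643, 0.654, 0.644, 0.644)
  p <- c(0.0053, 0.0058, 0.0055, 0.0056, 0.0043)
  o <- sample(5)
  expect_equal(overall_score(a, p)$overall, overall_score(a[o], p[o])$overall)
  # single data set: (AUROC + AUPR) / 2
  expect_equal(overall_score(0.8, 0.2)$overall, 0.5)
  expect_error(overall_score(c(0.5, 0), c(0.1, 0.1)), "non-positive")
})

test_that("regulatory-type fractions match hand enumeration", {
  uni <- pair_universe(c("T1", "T2", "T3"), c("g1", "g2", "g3"))
  gold <- gold_standard(c("T1", "T1", "T2", "T2", "T3"),
                        c("g1", "g2", "g3", "g1", "g2"),
                        c(1L, 1L, 1L, -1L, -1L))   # 3 activating, 2 repressing
  # perfect signed prediction
  perfect <- mk_net(gold$regulator, gold$target, seq(1, 0.2, length.out = 5),
                    gold$sign)
  tf <- type_fractions(perfect, gold, uni)
  expect_equal(tf[c("plus_fraction", "minus_fraction", "tp", "tn")],
               list(plus_fraction = 1, minus_fraction = 1, tp = 1, tn = 1))

  # all signs flipped: fractions drop to 0, TP unchanged
  flipped <- mk_net(gold$regulator, gold$target, perfect$weight, -gold$sign)
  tf2 <- type_fractions(flipped, gold, uni)
  expect_equal(tf2$plus_fraction, 0)
  expect_equal(tf2$minus_fraction, 0)
  expect_equal(tf2$tp, 1)

  # constructed 4-edge prediction:
  #   T1->g1 (+, correct), T1->g2 (-, wrong sign), T2->g1 (-, correct),
  #   T3->g3 (not in gold)
  pred <- mk_net(c("T1", "T1", "T2", "T3"), c("g1", "g2", "g1", "g3"),
                 c(1, 0.8, 0.6, 0.4), c(1L, -1L, -1L, 1L))
  tf3 <- type_fractions(pred, gold, uni)
  expect_equal(tf3$plus_fraction, 1 / 3)   # of 3 activating only T1->g1 correct
  expect_equal(tf3$minus_fraction, 1 / 2)  # of 2 repressing only T2->g1 correct
  expect_equal(tf3$tp, 3 / 5)              # T1->g1, T1->g2, T2->g1 predicted
  # universe minus self-pairs not applicable here (disjoint names): 9 pairs,
  # 4 non-gold; one of them (T3->g3) predicted
  expect_equal(tf3$tn, 3 / 4)

  expect_error(type_fractions(pred, gold_standard("T1", "g1"), uni),
               "no signed")
})
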