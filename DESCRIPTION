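Package: fusegrn
Title: Gene Regulatory Network Inference by Fused LASSO over Multiple
    Condition Data Sets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs sparse, signed transcription-factor to target
    gene regulatory networks from several time-resolved expression data
    sets gathered under different conditions, each with a matched
    control.  Per-condition regressions are stacked into one fused LASSO
    problem whose L1 penalty is weighted by the dissimilarity of
    empirical-Bayes differential-expression probability profiles
    (B-statistics), and whose fusion penalty drives the per-condition
    networks toward a common consensus.  Includes the local quadratic
    approximation solver with cross-validated penalty selection, an
    independent convex solver for verification, network assembly with
    edge normalization, a benchmarking suite (ROC/PR curves, AUROC,
    AUPR, TPR at fixed FPR, OverallScore, selector value, regulatory
    type accuracy), and a synthetic multi-condition study generator with
    planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    parallel
Suggests:
    testthat (>= 3.0.0),
    withr,
    limma,
    pROC,
    jsonlite
Config/testthat/edition: 3
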