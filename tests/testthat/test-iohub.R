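test_that("condition data sets round-trip through TSV and align by gene ID", {
  cd <- toy_dataset(genes = c("B", "A", "C"), N = 2, n_ctl = 2)
  tp <- withr::local_tempfile(fileext = ".tsv")
  cp <- withr::local_tempfile(fileext = ".tsv")
  write_condition_dataset(cd, tp, cp)
  back <- read_condition_dataset(tp, cp, condition = "toy")
  expect_equal(back$treatment, cd$treatment, tolerance = 1e-12)
  expect_equal(back$control, cd$control, tolerance = 1e-12)
  expect_identical(rownames(back$treatment), c("A", "B", "C"))
  expect_identical(ncol(back$treatment), 2L)
})

test_that("loader rejects malformed expression tables with named errors", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tt1\tt2", "A\t1\t2", "A\t3\t4"), path)
  expect_error(read_expression_matrix(path), "duplicate gene ID")

  writeLines(c("gene_id\tt1\tt2", "A\t1\tx"), path)
  expect_error(read_expression_matrix(path), "non-numeric")

  expect_error(read_expression_matrix(file.path(tempdir(), "nope.tsv")),
               "not found")

  tp <- withr::local_tempfile(fileext = ".tsv")
  cp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tt1", "A\t1", "B\t2"), tp)
  writeLines(c("gene_id\tc1", "A\t1", "C\t2"), cp)
  expect_error(read_condition_dataset(tp, cp), "gene sets")
})

test_that("gold standard parsing handles signs, duplicates and conflicts", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("A\tB\t+", "A\tC\t-"), path)
  gs <- read_gold_standard(path)
  expect_identical(gs$sign, c(1L, -1L))

  writeLines(c("A\tB\t+", "A\tB\t+"), path)
  expect_warning(gs <- read_gold_standard(path), "collapsed")
  expect_identical(nrow(gs), 1L)
  expect_identical(gs$sign, 1L)

  writeLines(c("A\tB\t+", "A\tB\t-"), path)
  expect_error(read_gold_standard(path), "conflicting")

  writeLines(c("A\tB\t%"), path)
  expect_error(read_gold_standard(path), "sign token")

  # byte-level round trip
  gs <- gold_standard(c("A", "A", "B"), c("B", "C", "C"), c(1L, -1L, NA))
  p1 <- withr::local_tempfile(fileext = ".tsv")
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_gold_standard(gs, p1)
  write_gold_standard(read_gold_standard(p1), p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("study assembly uses intersection semantics and is row-order invariant", {
  d1 <- toy_dataset(genes = c("A", "B", "C", "TF1"), seed = 1, condition = "c1")
  d2 <- toy_dataset(genes = c("C", "B", "A", "TF1"), seed = 2, condition = "c2")
  s <- multi_condition_study(list(d1, d2), regulator_ids = "TF1")
  expect_identical(s$genes, c("A", "B", "C", "TF1"))
  expect_identical(s$response_ids, c("A", "B", "C"))

  d3 <- toy_dataset(genes = c("A", "B", "TF1"), seed = 3, condition = "c2")
  expect_warning(s2 <- multi_condition_study(list(d1, d3), "TF1"),
                 "intersection")
  expect_identical(s2$genes, c("A", "B", "TF1"))

  expect_error(multi_condition_study(list(d1, d2), "TF9"), "regulator")
})

test_that("config files parse, validate and apply the documented defaults", {
  cfg <- study_config()
  expect_identical(cfg$lambda1_grid, c(0.05, 0.1, 0.5, 1, 1.5))
  expect_identical(cfg$lambda2_grid, c(0.1, 0.5, 1, 1.5, 2))
  expect_identical(cfg$cv_folds, 10L)
  expect_identical(cfg$consensus_mode, "max")
  expect_identical(cfg$top_n_edges, 100000L)

  path <- withr::local_tempfile(fileext = ".cfg")
  writeLines(c("# comment", "lambda1_grid = 0.1, 0.5",
               "cv_folds = 4", "consensus_mode = average",
               "standardize = off"), path)
  cfg2 <- read_study_config(path)
  expect_identical(cfg2$lambda1_grid, c(0.1, 0.5))
  expect_identical(cfg2$cv_folds, 4L)
  expect_identical(cfg2$consensus_mode, "average")
  expect_false(cfg2$standardize)

  writeLines("bogus_key = 1", path)
  expect_error(read_study_config(path), "unknown config key")
  expect_error(study_config(cv_folds = 1), "cv_folds")
  expect_error(study_config(lambda1_grid = numeric()), "non-empty")
  expect_error(study_config(lambda2_grid = c(-1, 1)), ">= 0")
})

test_that("the CLI runs simulate/probs/infer/evaluate end to end", {
  dir <- withr::local_tempdir()
  expect_identical(run_cli(c("simulate", "--seed", "7", "--out", dir,
                             "--tfs", "4", "--targets", "6")), 0L)
  cfg <- file.path(dir, "study.cfg")
  expect_true(file.exists(cfg))

  pdir <- file.path(dir, "probs")
  expect_identical(run_cli(c("probs", "--config", cfg, "--out", pdir)), 0L)
  expect_length(list.files(pdir, pattern = "_probs\\.tsv$"), 3L)

  netf <- file.path(dir, "net.tsv")
  expect_identical(run_cli(c("infer", "--config", cfg, "--out", netf)), 0L)
  expect_true(file.exists(netf))
  net <- read_network(netf)
  expect_gt(nrow(net), 0L)

  repf <- file.path(dir, "report.tsv")
  expect_identical(run_cli(c("evaluate", "--config", cfg,
                             "--network", netf,
                             "--gold", file.path(dir, "gold_standard.tsv"),
                             "--out", repf)), 0L)
  rep <- read.delim(repf)
  expect_true("auroc" %in% rep$metric)

  # failure modes: unknown subcommand, missing flag
  expect_identical(suppressMessages(run_cli("frobnicate")), 1L)
  expect_identical(suppressMessages(run_cli(c("infer", "--config", cfg))), 1L)
})

test_that("probability matrices round-trip and are validated", {
  m <- matrix(c(0, 1, 0.25, 0.75), 2, 2,
              dimnames = list(c("A", "B"), c("t1", "t2")))
  pr <- de_prob_matrix(m)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_probabilities(pr, path)
  back <- supply_probabilities(path)
  expect_equal(back$prob, m, tolerance = 1e-12)

  m[1, 1] <- 1.2
  writeLines(c("gene_id\tt1", "A\t1.2"), path)
  expect_error(supply_probabilities(path), "out of range")
})
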