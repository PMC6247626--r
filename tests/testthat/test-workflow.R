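# a grid profile small enough for unit testing: 2 chromosomes, 24 genes,
# 160 analyzed individuals
tiny_config <- function(seed = 501, ...) {
  default_config(seed = seed, n_chr = 2L, genes_per_chr = 12L,
                 rlfv_per_gene = 5L, n_common_per_chr = 40L,
                 n_sires = 16L, daughters_per_sire = 10L,
                 n_validation = 40L, replicates = 2L,
                 scenarios = "LQTN",
                 strategies = c("k50_only", "true_qtn", "mapped"),
                 random_genes_per_chr = 2L, ...)
}

test_that("configuration validation rejects inconsistent settings", {
  expect_error(default_config(scenarios = "XQTN"), "scenario")
  expect_error(default_config(strategies = "bogus"), "strategy")
  expect_error(default_config(n_sires = 2L, daughters_per_sire = 2L,
                              n_validation = 10L), "n_validation")
  expect_error(default_config(alpha = 1.5), "alpha")
  cfg <- tiny_config()
  expect_s3_class(cfg, "experiment_config")
})

test_that("replicate seeds are pure functions of their inputs", {
  s1 <- replicate_seed(42, "SQTN", 3)
  expect_identical(s1, replicate_seed(42, "SQTN", 3))
  expect_false(s1 == replicate_seed(42, "MQTN", 3))
  expect_false(s1 == replicate_seed(42, "SQTN", 4))
  expect_true(s1 >= 0 && s1 < 2^31)
  expect_error(replicate_seed(42, "nope", 1), "scenario")
})

test_that("strategy cells are deterministic and reuse replicate data", {
  cfg <- tiny_config()
  rs <- replicate_seed(cfg$seed, "LQTN", 1)
  c1 <- run_strategy_cell(cfg, "LQTN", "k50_only", rs)
  c2 <- run_strategy_cell(cfg, "LQTN", "k50_only", rs)
  expect_equal(c1, c2)
  expect_equal(c1$n_variants_g2, 0L)
  expect_true(is.na(c1$s2_rlfv))
  c3 <- run_strategy_cell(cfg, "LQTN", "true_qtn", rs)
  expect_gt(c3$n_variants_g2, 0)
  expect_false(is.na(c3$s2_rlfv))
})

test_that("the experiment grid runs, aggregates and reproduces itself", {
  cfg <- tiny_config()
  rep1 <- run_experiment(cfg)
  expect_s3_class(rep1, "experiment_report")
  expect_null(rep1$failed)
  expect_equal(nrow(rep1$cells), 2 * 3)  # replicates x strategies
  expect_setequal(unique(rep1$cells$strategy), cfg$strategies)
  expect_equal(nrow(rep1$summary), 3)
  # replicate mean/se agree with the evaluation helper
  k50 <- rep1$cells$reliability_pct[rep1$cells$strategy == "k50_only"]
  s <- replicate_summary(k50)
  row <- rep1$summary[rep1$summary$strategy == "k50_only", ]
  expect_equal(row$reliability_pct, unname(s["mean"]))
  expect_equal(row$reliability_se, unname(s["se"]))
  # a cell recomputed standalone matches the grid (per-replicate seeds pure)
  rs <- replicate_seed(cfg$seed, "LQTN", 2)
  cell <- run_strategy_cell(cfg, "LQTN", "true_qtn", rs)
  in_grid <- rep1$cells[rep1$cells$strategy == "true_qtn" &
                          rep1$cells$replicate == 2, ]
  expect_equal(cell$reliability, in_grid$reliability)
  expect_equal(cell$bias_slope, in_grid$bias_slope)
  # full rerun is identical
  rep2 <- run_experiment(cfg)
  expect_equal(rep1$cells, rep2$cells)
})

test_that("the mapping strategy sees only training individuals", {
  cfg <- tiny_config(seed = 502)
  rs <- replicate_seed(cfg$seed, "LQTN", 1)
  b <- rlfvgp:::simulate_replicate(cfg, "LQTN", rs)
  ph_train <- b$pheno[b$pheno$cohort == "training", ]
  A <- rlfvgp:::.bundle_kinship_null(b)
  s1 <- scan_genes(b$map, b$geno, ph_train, A, alpha = cfg$alpha)
  # perturbing validation phenotypes cannot change the scan
  b$pheno$y[b$pheno$cohort == "validation"] <-
    b$pheno$y[b$pheno$cohort == "validation"] + 100
  ph_train2 <- b$pheno[b$pheno$cohort == "training", ]
  s2 <- scan_genes(b$map, b$geno, ph_train2, A, alpha = cfg$alpha)
  expect_identical(s1$results, s2$results)
})

test_that("annotation and random-matched strategies produce valid cells", {
  cfg <- tiny_config(seed = 503,
                     strategies = c("all_genic", "annotation_medhigh",
                                    "random_matched"),
                     replicates = 1L)
  rep <- run_experiment(cfg)
  expect_null(rep$failed)
  expect_equal(nrow(rep$cells), 3)
  ag <- rep$cells[rep$cells$strategy == "all_genic", ]
  rm_ <- rep$cells[rep$cells$strategy == "random_matched", ]
  mh <- rep$cells[rep$cells$strategy == "annotation_medhigh", ]
  # matched control has (at most) the medium-to-high count by construction
  expect_lte(rm_$n_variants_g2, ag$n_variants_g2)
  expect_lte(mh$n_variants_g2, ag$n_variants_g2)
})

test_that("reports serialize to TSV + JSON", {
  cfg <- tiny_config(seed = 504, replicates = 1L,
                     strategies = c("k50_only", "true_qtn"))
  rep <- run_experiment(cfg)
  dir <- withr::local_tempdir()
  write_experiment_report(rep, dir)
  expect_true(file.exists(file.path(dir, "cells.tsv")))
  expect_true(file.exists(file.path(dir, "summary.tsv")))
  cells <- read_table_tsv(file.path(dir, "cells.tsv"))
  expect_equal(nrow(cells), nrow(rep$cells))
  cfg2 <- jsonlite::read_json(file.path(dir, "config.json"), simplifyVector = TRUE)
  expect_equal(cfg2$seed, 504)
})
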