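#' Default experiment configuration
#'
#' Desk-scale profile of the replicated simulation experiment: 29
#' autosomes, 20 genes per chromosome with 20 RLFV each (11,600 genic RLFV)
#' plus 150 common panel SNPs per chromosome (4350), 100 sire families with
#' 20 daughters each (2000 analyzed individuals, the 400 youngest held out
#' for validation), fertility-like variance components (genetic 145,
#' phenotypic 328.8), QTN variance 10% of the 50k genetic variance, and 10
#' replicates per scenario.
#'
#' @param seed master integer seed; all per-replicate seeds derive from it.
#' @param ... named overrides of any default field.
#' @return a named list of class `experiment_config`.
#' @export
default_config <- function(seed = 1, ...) {
  cfg <- list(
    seed = as.integer(seed),
    n_chr = 29L, genes_per_chr = 20L, rlfv_per_gene = 20L,
    n_common_per_chr = 150L,
    annotation_class_probs = c(high = 0.01, medium = 0.02, low = 0.97),
    n_sires = 100L, daughters_per_sire = 20L, n_validation = 400L,
    sigma2_g = 145, total_variance = 328.8, mean_r2_drp = 0.85,
    qtn_fraction = 0.10,
    scenarios = c("SQTN", "MQTN", "LQTN"),
    strategies = c("k50_only", "true_qtn", "qtn_plus_random", "mapped"),
    replicates = 10L,
    alpha = 0.01,
    maf_floor = 0.001, maf_ceiling = 0.05,
    random_genes_per_chr = 10L,
    kinship_null = "pedigree"
  )
  dots <- list(...)
  cfg[names(dots)] <- dots
  validate_config(cfg)
  structure(cfg, class = "experiment_config")
}

.known_strategies <- c("k50_only", "all_genic", "mapped", "annotation_high",
                       "annotation_medhigh", "random_matched", "true_qtn",
                       "qtn_plus_random")

#' Validate an experiment configuration
#'
#' @param config a configuration list.
#' @return the config, invisibly; errors on any invalid field.
#' @export
validate_config <- function(config) {
  stopifnot(config$replicates >= 1, config$n_chr >= 1,
            config$n_sires >= 1, config$daughters_per_sire >= 1)
  if (!all(config$scenarios %in% c("SQTN", "MQTN", "LQTN")))
    stop("unknown scenario label")
  if (!all(config$strategies %in% .known_strategies))
    stop("unknown strategy label; allowed: ", paste(.known_strategies, collapse = ", "))
  n <- config$n_sires * config$daughters_per_sire
  if (config$n_validation <= 0 || config$n_validation >= n)
    stop("n_validation must be in (0, n analyzed individuals)")
  if (!(config$alpha > 0 && config$alpha < 1)) stop("alpha must be in (0, 1)")
  invisible(config)
}

#' Per-replicate seed derived from the master seed
#'
#' A pure function of (master seed, scenario, replicate index), so any cell
#' of the experiment grid can be re-run independently.
#'
#' @param master_seed master integer seed.
#' @param scenario scenario label.
#' @param replicate replicate index (1-based).
#' @return integer seed below 2^31.
#' @export
replicate_seed <- function(master_seed, scenario, replicate) {
  s_idx <- match(scenario, c("SQTN", "MQTN", "LQTN"))
  if (is.na(s_idx)) stop("unknown scenario label")
  as.integer((as.numeric(master_seed) + 104729 * s_idx + 7919 * replicate) %% 2101234567)
}

# Generate all per-replicate data shared across strategies: genome map,
# population, DRP, QTN overlay, RLFV window and the common-panel GRM.
# Returned as an environment so lazily computed pieces (pedigree A, the
# mapping scan) are memoized across strategies of the same replicate.
simulate_replicate <- function(config, scenario, rep_seed) {
  b <- new.env(parent = emptyenv())
  b$config <- config
  b$scenario <- scenario
  b$rep_seed <- rep_seed
  sub_seed <- function(k) as.integer((as.numeric(rep_seed) + 7717 * k) %% 2101234567)
  b$map <- simulate_genome_map(
    n_chr = config$n_chr, genes_per_chr = config$genes_per_chr,
    rlfv_per_gene = config$rlfv_per_gene,
    n_common_per_chr = config$n_common_per_chr,
    annotation_class_probs = config$annotation_class_probs,
    seed = sub_seed(1))
  pop <- simulate_population(b$map, n_sires = config$n_sires,
                             daughters_per_sire = config$daughters_per_sire,
                             seed = sub_seed(2))
  b$pedigree <- pop$pedigree
  off <- pop$pedigree$id[pop$pedigree$generation == 1L]
  b$geno <- pop$genotypes[off, , drop = FALSE]
  rm(pop)
  common_ids <- b$map$variants$id[b$map$variants$panel == "common_50k"]
  b$common_ids <- common_ids
  pheno <- simulate_drp(b$geno[, common_ids, drop = FALSE],
                        sigma2_g = config$sigma2_g,
                        total_variance = config$total_variance,
                        mean_r2_drp = config$mean_r2_drp,
                        n_validation = config$n_validation,
                        seed = sub_seed(3))
  b$qtn <- simulate_qtn_scenario(b$map, b$geno, scenario,
                                 fraction = config$qtn_fraction,
                                 sigma2_50k = config$sigma2_g,
                                 seed = sub_seed(4))
  b$pheno <- compose_phenotype(pheno, b$qtn)
  b$training_ids <- b$pheno$id[b$pheno$cohort == "training"]
  b$validation_ids <- b$pheno$id[b$pheno$cohort == "validation"]
  b$rlfv <- filter_rlfv(b$geno, config$maf_floor, config$maf_ceiling)
  b$rlfv$ids <- setdiff(b$rlfv$ids, common_ids)
  b$rlfv$count <- length(b$rlfv$ids)
  b$G1 <- vanraden_grm(b$geno, common_ids)
  b$sub_seed <- sub_seed
  b
}

# pedigree A among analyzed individuals, computed once per replicate
.bundle_kinship_null <- function(b) {
  if (is.null(b$A_null)) {
    if (identical(b$config$kinship_null, "pedigree")) {
      A <- pedigree_a_matrix(b$pedigree)
      b$A_null <- relmat_subset(A, rownames(b$geno))
    } else {
      b$A_null <- b$G1
    }
  }
  b$A_null
}

# mapping scan on the training cohort, memoized per replicate
.bundle_mapped_genes <- function(b) {
  if (is.null(b$scan)) {
    K <- .bundle_kinship_null(b)
    ph_train <- b$pheno[b$pheno$cohort == "training", , drop = FALSE]
    b$scan <- scan_genes(b$map, b$geno, ph_train, K, alpha = b$config$alpha)
  }
  b$scan$mapped_genes
}

# variant set that defines the second GRM for a strategy (NULL = Model 1)
.strategy_variants <- function(b, strategy) {
  cfg <- b$config
  switch(strategy,
    k50_only = NULL,
    true_qtn = .variant_subset(b$qtn$qtn_ids, "true_qtn", "true_qtn"),
    qtn_plus_random = {
      set.seed(b$sub_seed(5))
      genes <- b$map$genes
      pool <- genes[!(genes$gene_id %in% b$qtn$genes), , drop = FALSE]
      noise_genes <- unlist(lapply(split(pool$gene_id, pool$chr), function(g) {
        if (length(g) < cfg$random_genes_per_chr)
          stop("not enough non-causal genes per chromosome for the random-gene control")
        sample(g, cfg$random_genes_per_chr)
      }), use.names = FALSE)
      v <- b$map$variants
      noise_ids <- v$id[!is.na(v$gene) & v$gene %in% noise_genes]
      .variant_subset(c(b$qtn$qtn_ids, noise_ids), "qtn_plus_random", "qtn_plus_random",
                      params = list(n_noise_genes = length(noise_genes)))
    },
    mapped = select_by_mapping(b$rlfv, b$map, .bundle_mapped_genes(b)),
    all_genic = select_genic(b$rlfv, b$map),
    annotation_high = select_by_annotation(b$rlfv, b$map, "high"),
    annotation_medhigh = select_by_annotation(b$rlfv, b$map, c("high", "medium")),
    random_matched = {
      target <- select_by_annotation(b$rlfv, b$map, c("high", "medium"))$count
      select_random_matched(b$rlfv, min(target, b$rlfv$count), seed = b$sub_seed(6))
    },
    stop("unknown strategy: ", strategy)
  )
}

# fit, predict and evaluate one (scenario, strategy) cell on prepared data
.run_cell_on <- function(b, strategy) {
  cfg <- b$config
  subset <- .strategy_variants(b, strategy)
  Ks <- list(g50k = b$G1)
  n_g2 <- 0L
  if (!is.null(subset) && subset$count > 0) {
    p2 <- colMeans(b$geno[, subset$ids, drop = FALSE]) / 2
    poly <- subset$ids[p2 > 0 & p2 < 1]
    if (length(poly) > 0) {
      Ks$rlfv <- vanraden_grm(b$geno, poly)
      n_g2 <- length(poly)
    }
  }
  tr <- b$training_ids
  va <- b$validation_ids
  ph <- b$pheno
  y_tr <- ph$y[match(tr, ph$id)]
  Ks_tr <- lapply(Ks, relmat_subset, ids = tr)
  fit <- reml_fit(y_tr, Ks_tr)
  pred <- predict_gebv(fit, Ks, tr, va)
  y_va <- ph$y[match(va, ph$id)]
  r2_va <- mean(ph$r2_drp[match(va, ph$id)])
  rel <- reliability(pred$gebv, y_va, r2_va)
  data.frame(
    scenario = b$scenario, strategy = strategy, rep_seed = b$rep_seed,
    n_variants_g2 = n_g2,
    s2_g50k = unname(fit$varcomp["g50k"]),
    s2_rlfv = if ("rlfv" %in% names(fit$varcomp)) unname(fit$varcomp["rlfv"]) else NA_real_,
    s2_e = unname(fit$varcomp["residual"]),
    converged = fit$converged,
    reliability = rel, reliability_pct = 100 * rel,
    accuracy = sqrt(rel),
    accuracy_se = accuracy_se(rel, length(tr), sqrt(r2_va)),
    bias_slope = bias_slope(pred$gebv, y_va),
    n_training = length(tr), mean_r2_drp_val = r2_va,
    stringsAsFactors = FALSE
  )
}

#' Run one cell of the experiment grid
#'
#' Generates the replicate's data from its seed, builds the strategy's
#' second GRM (if any), fits the one- or two-component GBLUP model by REML
#' on the training cohort, predicts validation GEBV and evaluates
#' reliability and bias. Strategies: `k50_only` (reference Model 1),
#' `true_qtn` (QTN known without error), `qtn_plus_random` (QTN plus RLFV
#' from random non-causal genes: the false-positive noise control),
#' `mapped` (RLFV of genes with scan p < alpha), `all_genic`,
#' `annotation_high`, `annotation_medhigh`, `random_matched`.
#'
#' @param config an `experiment_config`.
#' @param scenario `"SQTN"`, `"MQTN"` or `"LQTN"`.
#' @param strategy one of the strategy labels above.
#' @param replicate_seed integer seed for the replicate (see
#'   [replicate_seed()]).
#' @return one-row data.frame with variance components, reliability (0-1
#'   and percent), accuracy and its SE, and the bias slope.
#' @export
run_strategy_cell <- function(config, scenario, strategy, replicate_seed) {
  validate_config(config)
  b <- simulate_replicate(config, scenario, replicate_seed)
  .run_cell_on(b, strategy)
}

#' Run the replicated experiment grid
#'
#' Iterates scenarios x strategies x replicates, sharing each replicate's
#' simulated data (and its mapping scan) across strategies, and aggregates
#' per-cell results into replicate means and standard errors. A failing
#' cell is recorded with its error message and does not abort the grid.
#'
#' @param config an `experiment_config`.
#' @param verbose print per-cell progress to stderr.
#' @return object of class `experiment_report`: list with `cells` (one row
#'   per scenario x strategy x replicate), `summary` (replicate mean and
#'   `sd/sqrt(k)` of reliability and bias slope per cell of the grid),
#'   `failed` (data.frame of failed cells, if any) and `config`.
#' @export
run_experiment <- function(config, verbose = FALSE) {
  validate_config(config)
  cells <- list()
  failed <- list()
  for (scen in config$scenarios) {
    for (rep_i in seq_len(config$replicates)) {
      rs <- replicate_seed(config$seed, scen, rep_i)
      b <- simulate_replicate(config, scen, rs)
      for (strat in config$strategies) {
        t0 <- proc.time()[3]
        res <- tryCatch(.run_cell_on(b, strat), error = function(e) e)
        if (inherits(res, "error")) {
          failed[[length(failed) + 1]] <- data.frame(
            scenario = scen, strategy = strat, replicate = rep_i,
            reason = conditionMessage(res), stringsAsFactors = FALSE)
        } else {
          res$replicate <- rep_i
          cells[[length(cells) + 1]] <- res
        }
        if (verbose)
          message(sprintf("[%s | %s | rep %d] %.1fs", scen, strat, rep_i,
                          proc.time()[3] - t0))
      }
      rm(b)
    }
  }
  cells <- if (length(cells)) do.call(rbind, cells) else NULL
  summary <- NULL
  if (!is.null(cells)) {
    grp <- split(cells, list(cells$scenario, cells$strategy), drop = TRUE)
    summary <- do.call(rbind, lapply(grp, function(g) {
      rel <- if (nrow(g) >= 2) replicate_summary(g$reliability_pct) else
        c(mean = mean(g$reliability_pct), se = NA_real_)
      sl <- if (nrow(g) >= 2) replicate_summary(g$bias_slope) else
        c(mean = mean(g$bias_slope), se = NA_real_)
      data.frame(scenario = g$scenario[1], strategy = g$strategy[1],
                 replicates = nrow(g),
                 reliability_pct = rel["mean"], reliability_se = rel["se"],
                 bias_slope = sl["mean"], bias_slope_se = sl["se"],
                 stringsAsFactors = FALSE)
    }))
    rownames(summary) <- NULL
  }
  structure(list(cells = cells, summary = summary,
                 failed = if (length(failed)) do.call(rbind, failed) else NULL,
                 config = config),
            class = "experiment_report")
}

#' @export
print.experiment_report <- function(x, ...) {
  cat("experiment_report\n")
  if (!is.null(x$summary)) {
    s <- x$summary
    s$reliability_pct <- round(s$reliability_pct, 1)
    s$reliability_se <- round(s$reliability_se, 2)
    s$bias_slope <- round(s$bias_slope, 3)
    s$bias_slope_se <- round(s$bias_slope_se, 3)
    print(s)
  }
  if (!is.null(x$failed)) {
    cat("failed cells:\n")
    print(x$failed)
  }
  invisible(x)
}

#' Write an experiment report to disk
#'
#' Writes `cells.tsv`, `summary.tsv` and `config.json` under `out_dir`.
#'
#' @param report an `experiment_report`.
#' @param out_dir output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_experiment_report <- function(report, out_dir) {
  stopifnot(inherits(report, "experiment_report"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(report$cells))
    data.table::fwrite(report$cells, file.path(out_dir, "cells.tsv"), sep = "\t")
  if (!is.null(report$summary))
    data.table::fwrite(report$summary, file.path(out_dir, "summary.tsv"), sep = "\t")
  cfg <- unclass(report$config)
  cfg$annotation_class_probs <- as.list(cfg$annotation_class_probs)
  jsonlite::write_json(cfg, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
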