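#' Simulate a genome map with genes, RLFV and a common SNP panel
#'
#' Builds the marker map that all downstream simulation assumes: a set of
#' autosomes, each carrying `genes_per_chr` non-overlapping genes whose
#' variants are rare or low-frequency (RLFV, target minor allele frequency in
#' \[0.001, 0.05)), plus an intergenic panel of common SNPs (target MAF >=
#' 0.05) emulating a 50k genotyping array. Each RLFV receives an annotation
#' class (`high`, `medium` or `low` impact) drawn independently with the
#' supplied probabilities; common panel SNPs are labelled `intergenic`.
#'
#' @param n_chr number of autosomes (cattle have 29).
#' @param genes_per_chr number of genes per chromosome.
#' @param rlfv_per_gene number of RLFV per gene.
#' @param n_common_per_chr number of common panel SNPs per chromosome.
#' @param annotation_class_probs named numeric vector with elements `high`,
#'   `medium`, `low`, summing to 1; per-RLFV annotation class probabilities.
#' @param chr_length chromosome length in base pairs.
#' @param seed integer seed; the map is deterministic given the seed.
#'
#' @return an object of class `genome_map`: a list with elements
#'   `chromosomes` (character vector), `genes` (data.frame: `gene_id`, `chr`,
#'   `start`, `end`, `n_rlfv`) and `variants` (data.frame: `id`, `chr`,
#'   `pos`, `target_maf`, `class`, `panel`, `gene`), with variants sorted by
#'   chromosome and position.
#' @export
simulate_genome_map <- function(n_chr = 29, genes_per_chr = 20, rlfv_per_gene = 20,
                                n_common_per_chr = 150,
                                annotation_class_probs = c(high = 0.01, medium = 0.02, low = 0.97),
                                chr_length = 1e8, seed = 1) {
  stopifnot(n_chr >= 1, genes_per_chr >= 1, rlfv_per_gene >= 1, n_common_per_chr >= 1)
  p <- annotation_class_probs[c("high", "medium", "low")]
  if (anyNA(p)) stop("annotation_class_probs must be named with 'high', 'medium', 'low'")
  if (abs(sum(p) - 1) > 1e-9) stop("annotation class probabilities must sum to 1")

  set.seed(as.integer(seed))
  chroms <- sprintf("chr%d", seq_len(n_chr))
  gene_rows <- vector("list", n_chr)
  var_rows <- vector("list", n_chr)
  # each gene lives inside its own equal slot of the chromosome so genes
  # never overlap and variant positions stay unique
  slot <- floor(chr_length / genes_per_chr)
  gene_span <- max(2L * rlfv_per_gene, min(50000L, slot %/% 4L))
  for (c_i in seq_len(n_chr)) {
    starts <- (seq_len(genes_per_chr) - 1L) * slot +
      sample.int(slot - gene_span - 1L, genes_per_chr, replace = TRUE)
    ends <- starts + gene_span
    gid <- sprintf("%s_g%d", chroms[c_i], seq_len(genes_per_chr))
    rl_pos <- lapply(seq_len(genes_per_chr), function(g)
      sort(sample(seq.int(starts[g] + 1L, ends[g]), rlfv_per_gene)))
    rl <- data.frame(
      chr = chroms[c_i],
      pos = unlist(rl_pos),
      target_maf = stats::runif(genes_per_chr * rlfv_per_gene, 0.001, 0.05),
      class = sample(c("high", "medium", "low"), genes_per_chr * rlfv_per_gene,
                     replace = TRUE, prob = p),
      panel = "sequence_rlfv",
      gene = rep(gid, each = rlfv_per_gene),
      stringsAsFactors = FALSE
    )
    # common panel SNPs are placed between genes (intergenic)
    gaps <- setdiff(seq.int(1L, chr_length, by = max(1L, chr_length %/% (50L * n_common_per_chr))),
                    unlist(rl_pos))
    cm <- data.frame(
      chr = chroms[c_i],
      pos = sort(sample(gaps, n_common_per_chr)),
      target_maf = stats::runif(n_common_per_chr, 0.05, 0.5),
      class = "intergenic",
      panel = "common_50k",
      gene = NA_character_,
      stringsAsFactors = FALSE
    )
    v <- rbind(rl, cm)
    v <- v[order(v$pos), , drop = FALSE]
    var_rows[[c_i]] <- v
    gene_rows[[c_i]] <- data.frame(gene_id = gid, chr = chroms[c_i],
                                   start = starts, end = ends,
                                   n_rlfv = rlfv_per_gene, stringsAsFactors = FALSE)
  }
  variants <- do.call(rbind, var_rows)
  variants$id <- sprintf("%s_%d", variants$chr, variants$pos)
  rownames(variants) <- NULL
  variants <- variants[, c("id", "chr", "pos", "target_maf", "class", "panel", "gene")]
  structure(list(chromosomes = chroms,
                 genes = do.call(rbind, gene_rows),
                 variants = variants),
            class = "genome_map")
}

#' @export
print.genome_map <- function(x, ...) {
  cat(sprintf("genome_map: %d chromosomes, %d genes, %d variants (%d RLFV, %d common)\n",
              length(x$chromosomes), nrow(x$genes), nrow(x$variants),
              sum(x$variants$panel == "sequence_rlfv"),
              sum(x$variants$panel == "common_50k")))
  invisible(x)
}

# Bernoulli transmission of one gamete per locus given parent dosages (0/1/2)
.transmit <- function(G) {
  (matrix(stats::runif(length(G)), nrow(G)) < G / 2) + 0L
}

#' Simulate a two-generation half-sib population with gene dropping
#'
#' Founder sires and dams are drawn in linkage equilibrium, per locus
#' `Binomial(2, target MAF)`. Each daughter receives one gamete from her sire
#' and one from her own (unique) founder dam, giving paternal half-sib
#' families typical of dairy cattle. Within-chromosome linkage disequilibrium
#' therefore arises only from family co-segregation, which is the mechanism
#' by which a common-SNP panel captures rare-variant effects.
#'
#' @param genome_map a `genome_map`.
#' @param n_sires number of founder sires.
#' @param daughters_per_sire number of daughters per sire (0 = founders only).
#' @param seed integer seed.
#'
#' @return list with `pedigree` (data.frame: `id`, `sire`, `dam`,
#'   `generation`; `NA` parent = unknown founder parent), `genotypes`
#'   (integer matrix, individuals x variants, allele dosage 0/1/2 of the
#'   counted allele, rownames = individual IDs, colnames = variant IDs) and
#'   `realized_maf` (named vector of observed minor allele frequencies).
#' @export
simulate_population <- function(genome_map, n_sires, daughters_per_sire, seed = 1) {
  stopifnot(inherits(genome_map, "genome_map"), n_sires >= 1, daughters_per_sire >= 0)
  m <- nrow(genome_map$variants)
  if (m == 0) stop("genome map has no variants")
  set.seed(as.integer(seed))
  maf <- genome_map$variants$target_maf
  n_off <- n_sires * daughters_per_sire
  n_dams <- n_off
  nf <- n_sires + n_dams
  # Binomial(2, maf) as the sum of two Bernoulli gametes, drawn with runif
  # (markedly faster than rbinom at this scale)
  pm <- rep(maf, each = nf)
  founders <- matrix((stats::runif(nf * m) < pm) + (stats::runif(nf * m) < pm),
                     nrow = nf, ncol = m)
  sire_ids <- sprintf("S%04d", seq_len(n_sires))
  dam_ids <- if (n_dams > 0) sprintf("D%05d", seq_len(n_dams)) else character(0)
  ped <- data.frame(id = c(sire_ids, dam_ids),
                    sire = NA_character_, dam = NA_character_,
                    generation = 0L, stringsAsFactors = FALSE)
  geno <- founders
  ids <- c(sire_ids, dam_ids)
  if (n_off > 0) {
    sire_idx <- rep(seq_len(n_sires), each = daughters_per_sire)
    dam_idx <- n_sires + seq_len(n_off)
    # chunk over variants to bound the transient runif allocations
    child <- matrix(0L, n_off, m)
    chunk <- 4000L
    for (j0 in seq.int(1L, m, by = chunk)) {
      j <- seq.int(j0, min(m, j0 + chunk - 1L))
      child[, j] <- .transmit(founders[sire_idx, j, drop = FALSE]) +
        .transmit(founders[dam_idx, j, drop = FALSE])
    }
    off_ids <- sprintf("O%05d", seq_len(n_off))
    ped <- rbind(ped, data.frame(id = off_ids,
                                 sire = sire_ids[sire_idx],
                                 dam = dam_ids,
                                 generation = 1L, stringsAsFactors = FALSE))
    geno <- rbind(founders, child)
    ids <- c(sire_ids, dam_ids, off_ids)
  }
  storage.mode(geno) <- "integer"
  dimnames(geno) <- list(ids, genome_map$variants$id)
  p <- colMeans(geno) / 2
  list(pedigree = ped, genotypes = geno, realized_maf = pmin(p, 1 - p))
}

#' Simulate de-regressed proofs (DRP) with per-individual reliabilities
#'
#' A polygenic true breeding value (TBV) is built from the common panel:
#' per-marker effects are standard normal on centered dosages, and the TBV
#' vector is rescaled so its sample variance equals `sigma2_g` exactly. Each
#' individual then receives a DRP equal to its TBV plus noise whose variance
#' follows from the individual's DRP reliability,
#' `var_noise = sigma2_g * (1 - r2) / r2`, with reliabilities drawn from a
#' narrow Beta distribution around `mean_r2_drp`. With `mean_r2_drp = 1` the
#' DRP equal the TBV exactly. To emulate a raw phenotype with heritability
#' `sigma2_g / total_variance`, set `mean_r2_drp` to that ratio, which makes
#' the phenotypic variance equal `total_variance`.
#'
#' The youngest `n_validation` individuals by birth-order rank form the
#' validation cohort; the rest are training.
#'
#' @param genotypes_common dosage matrix (individuals x common SNPs) with
#'   individual IDs as rownames.
#' @param sigma2_g additive genetic variance of the trait (trait units^2).
#' @param total_variance phenotypic variance of the underlying trait; must
#'   exceed `sigma2_g`. The implied heritability is `sigma2_g/total_variance`.
#' @param mean_r2_drp mean DRP reliability in (0, 1].
#' @param n_validation size of the validation cohort (youngest individuals).
#' @param seed integer seed.
#' @param beta_concentration concentration of the Beta distribution of
#'   per-individual reliabilities (larger = narrower).
#'
#' @return data.frame with columns `id`, `birth_rank`, `tbv`, `r2_drp`,
#'   `drp`, `y` (composed phenotype, equal to `drp` until a QTN overlay is
#'   added) and `cohort` (`"training"`/`"validation"`).
#' @export
simulate_drp <- function(genotypes_common, sigma2_g, total_variance,
                         mean_r2_drp = 0.85, n_validation = 1000, seed = 1,
                         beta_concentration = 200) {
  n <- nrow(genotypes_common)
  if (is.null(n) || n < 2) stop("need a genotype matrix with >= 2 individuals")
  if (!(sigma2_g > 0) || !(total_variance > sigma2_g))
    stop("need 0 < sigma2_g < total_variance")
  if (!(mean_r2_drp > 0 && mean_r2_drp <= 1)) stop("mean_r2_drp must be in (0, 1]")
  if (n_validation < 0 || n_validation >= n) stop("n_validation must be in [0, n)")
  set.seed(as.integer(seed))
  X <- genotypes_common
  storage.mode(X) <- "double"
  u <- stats::rnorm(ncol(X))
  tbv <- as.vector(X %*% u)
  tbv <- tbv - mean(tbv)
  v <- stats::var(tbv)
  if (v <= 0) stop("polygenic TBV has zero variance (monomorphic panel?)")
  tbv <- tbv * sqrt(sigma2_g / v)
  if (mean_r2_drp == 1) {
    r2 <- rep(1, n)
    noise <- numeric(n)
  } else {
    r2 <- stats::rbeta(n, mean_r2_drp * beta_concentration,
                       (1 - mean_r2_drp) * beta_concentration)
    r2 <- pmin(pmax(r2, 1e-3), 1)
    noise <- stats::rnorm(n, sd = sqrt(sigma2_g * (1 - r2) / r2))
  }
  drp <- tbv + noise
  # births are exchangeable across families: the youngest block then contains
  # the younger members of many half-sib families, so validation individuals
  # remain related to training individuals as in the real population
  birth_rank <- sample.int(n)
  cohort <- ifelse(birth_rank > n - n_validation, "validation", "training")
  data.frame(id = rownames(genotypes_common), birth_rank = birth_rank,
             tbv = tbv, r2_drp = r2, drp = drp, y = drp, cohort = cohort,
             stringsAsFactors = FALSE)
}

#' Simulate causal rare-variant (QTN) scenarios
#'
#' Selects genes according to the scenario, declares every RLFV in the
#' selected genes a QTN, draws per-QTN allele substitution effects from a
#' standard normal, and scales the resulting true breeding values
#' `TBV_Q = M_Q \%*\% alpha` so their sample variance equals exactly
#' `fraction * sigma2_50k` (relative error < 1e-10).
#'
#' Scenarios:
#' \describe{
#'   \item{SQTN}{many small effects: `k` genes per chromosome with `k` drawn
#'     once per call uniformly from \{7, 8, 9, 10\}.}
#'   \item{MQTN}{one gene per chromosome.}
#'   \item{LQTN}{nine genes sampled across the whole genome.}
#' }
#'
#' @param genome_map a `genome_map`.
#' @param genotypes dosage matrix over the individuals whose phenotypes will
#'   receive the overlay (rows) and at least all RLFV columns.
#' @param scenario one of `"SQTN"`, `"MQTN"`, `"LQTN"`.
#' @param fraction fraction of `sigma2_50k` the QTN must jointly explain
#'   (the design value is 0.10).
#' @param sigma2_50k genetic variance captured by the common panel that the
#'   QTN variance is expressed relative to.
#' @param seed integer seed.
#'
#' @return an object of class `qtn_set`: list with `scenario`, `genes`
#'   (selected gene IDs), `qtn_ids` (variant IDs), `alpha` (scaled effects),
#'   `tbv_q` (named per-individual vector), `target_fraction`, `sigma2_50k`,
#'   `realized_var` and, for SQTN, `genes_per_chr_drawn`.
#' @export
simulate_qtn_scenario <- function(genome_map, genotypes, scenario,
                                  fraction = 0.10, sigma2_50k, seed = 1) {
  scenario <- match.arg(scenario, c("SQTN", "MQTN", "LQTN"))
  if (!(fraction > 0)) stop("fraction must be > 0")
  stopifnot(inherits(genome_map, "genome_map"))
  set.seed(as.integer(seed))
  genes <- genome_map$genes
  k_drawn <- NA_integer_
  if (scenario == "LQTN") {
    if (nrow(genes) < 9) stop("fewer genes available than requested")
    sel <- sample(genes$gene_id, 9)
  } else {
    per_chr <- if (scenario == "MQTN") 1L else {
      k_drawn <- sample(7:10, 1)
      k_drawn
    }
    sel <- unlist(lapply(split(genes$gene_id, genes$chr), function(g) {
      if (length(g) < per_chr) stop("fewer genes available than requested")
      sample(g, per_chr)
    }), use.names = FALSE)
  }
  qtn_ids <- genome_map$variants$id[!is.na(genome_map$variants$gene) &
                                      genome_map$variants$gene %in% sel]
  M <- genotypes[, qtn_ids, drop = FALSE]
  storage.mode(M) <- "double"
  alpha <- stats::rnorm(length(qtn_ids))
  tbv_q <- as.vector(M %*% alpha)
  v <- stats::var(tbv_q)
  if (!(v > 0)) stop("all selected genes are monomorphic; cannot scale QTN variance")
  scl <- sqrt(fraction * sigma2_50k / v)
  tbv_q <- tbv_q * scl
  names(tbv_q) <- rownames(genotypes)
  structure(list(scenario = scenario, genes = sort(sel), qtn_ids = qtn_ids,
                 alpha = alpha * scl, tbv_q = tbv_q,
                 target_fraction = fraction, sigma2_50k = sigma2_50k,
                 realized_var = stats::var(tbv_q),
                 genes_per_chr_drawn = k_drawn),
            class = "qtn_set")
}

#' @export
print.qtn_set <- function(x, ...) {
  cat(sprintf("qtn_set [%s]: %d genes, %d QTN, var(TBV_Q) = %.4g (target %.4g)\n",
              x$scenario, length(x$genes), length(x$qtn_ids),
              x$realized_var, x$target_fraction * x$sigma2_50k))
  invisible(x)
}

#' Add a QTN overlay to simulated phenotypes
#'
#' Composes the analysed phenotype `y = DRP + TBV_Q` individual by
#' individual. All other columns are returned unchanged.
#'
#' @param phenotypes data.frame as returned by [simulate_drp()].
#' @param qtn_set a `qtn_set` whose `tbv_q` covers the same individuals.
#' @return the phenotype data.frame with its `y` column replaced by
#'   `drp + tbv_q`.
#' @export
compose_phenotype <- function(phenotypes, qtn_set) {
  stopifnot(inherits(qtn_set, "qtn_set"))
  idx <- match(phenotypes$id, names(qtn_set$tbv_q))
  if (anyNA(idx) || length(qtn_set$tbv_q) != nrow(phenotypes))
    stop("individual IDs of phenotypes and QTN set do not match")
  phenotypes$y <- phenotypes$drp + unname(qtn_set$tbv_q[idx])
  phenotypes
}
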