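# shared small fixtures, built in code at test time

tiny_map <- function(seed = 101, n_chr = 2, genes_per_chr = 10, rlfv_per_gene = 5,
                     n_common_per_chr = 25) {
  simulate_genome_map(n_chr = n_chr, genes_per_chr = genes_per_chr,
                      rlfv_per_gene = rlfv_per_gene,
                      n_common_per_chr = n_common_per_chr, seed = seed)
}

tiny_pop <- function(map = tiny_map(), n_sires = 10, daughters_per_sire = 10,
                     seed = 202) {
  simulate_population(map, n_sires = n_sires,
                      daughters_per_sire = daughters_per_sire, seed = seed)
}

offspring_geno <- function(pop) {
  off <- pop$pedigree$id[pop$pedigree$generation == 1L]
  pop$genotypes[off, , drop = FALSE]
}

# random founder dosage matrix without any map bookkeeping
random_dosages <- function(n, m, seed = 1, maf = NULL) {
  set.seed(seed)
  if (is.null(maf)) maf <- runif(m, 0.05, 0.5)
  g <- matrix(rbinom(n * m, 2L, rep(maf, each = n)), n, m,
              dimnames = list(sprintf("i%03d", seq_len(n)),
                              sprintf("v%05d", seq_len(m))))
  g
}

# independent brute-force VanRaden GRM used as oracle
grm_oracle <- function(X) {
  X <- matrix(as.numeric(X), nrow(X), ncol(X), dimnames = dimnames(X))
  p <- apply(X, 2, function(col) sum(col) / (2 * length(col)))
  Z <- X
  for (j in seq_len(ncol(X))) Z[, j] <- X[, j] - 2 * p[j]
  den <- 0
  for (j in seq_len(ncol(X))) den <- den + 2 * p[j] * (1 - p[j])
  (Z %*% t(Z)) / den
}
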