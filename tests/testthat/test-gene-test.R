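test_that("mixture-of-chi-squares survival matches exact chi-square cases", {
  # single weight: Q / lambda ~ chi2_1
  r1 <- pchisqmix(7.1, 2.5)
  expect_equal(r1$p, pchisq(7.1 / 2.5, 1, lower.tail = FALSE), tolerance = 1e-8)
  # equal weights: Q / lambda ~ chi2_m
  r2 <- pchisqmix(15, rep(1.3, 6))
  expect_equal(r2$p, pchisq(15 / 1.3, 6, lower.tail = FALSE), tolerance = 1e-8)
  # unequal weights against an independent Monte Carlo estimate
  lam <- c(3.2, 1.1, 0.4, 0.05)
  set.seed(5)
  sim <- colSums(lam * matrix(rchisq(4 * 5e5, 1), 4))
  for (q in c(2, 8, 20)) {
    mc <- mean(sim > q)
    se <- sqrt(mc * (1 - mc) / 5e5)
    expect_lt(abs(pchisqmix(q, lam)$p - mc), 4 * se)
  }
  expect_equal(pchisqmix(0, lam)$p, 1)
  expect_equal(pchisqmix(5, numeric(0))$p, 1)
})

test_that("null model reduces to GLS closed forms on iid data", {
  set.seed(9)
  y <- rnorm(60, mean = 4)
  nf <- fit_null_model(y, kinship = diag(60))
  # intercept-only GLS mean with V proportional to I is the sample mean
  expect_equal(nf$gamma[1], mean(y), tolerance = 1e-6)
  # the REML fit maximizes the restricted likelihood: no worse than the
  # boundary (s2_a ~ 0) or an equal-split alternative
  ll_fit <- restricted_loglik(y, diag(60), c(nf$s2a, nf$s2e))
  expect_gte(ll_fit, restricted_loglik(y, diag(60), c(1e-8, var(y))) - 1e-6)
  expect_gte(ll_fit, restricted_loglik(y, diag(60), c(var(y) / 2, var(y) / 2)) - 1e-6)
})

test_that("score test handles degenerate, duplicated and flipped dosages", {
  set.seed(13)
  n <- 50
  y <- rnorm(n)
  nf <- fit_null_model(y, kinship = diag(n))
  # all-zero gene: no signal possible
  M0 <- matrix(0L, n, 4)
  r0 <- gene_score_test(nf, M0)
  expect_equal(r0$p, 1)
  expect_equal(r0$status, "degenerate")
  # monomorphic-but-nonzero gene is degenerate too (projection removes it)
  r2 <- gene_score_test(nf, matrix(2L, n, 3))
  expect_equal(r2$status, "degenerate")
  M <- matrix(rbinom(n * 3, 2, 0.1), n, 3)
  r <- gene_score_test(nf, M)
  expect_equal(r$status, "ok")
  expect_true(r$p > 0 && r$p <= 1)
  # duplicating every variant doubles Q and the eigenvalues consistently
  rd <- gene_score_test(nf, cbind(M, M))
  expect_equal(rd$Q, 2 * r$Q, tolerance = 1e-10)
  expect_equal(sort(rd$lambda), sort(2 * r$lambda), tolerance = 1e-8)
  expect_equal(rd$p, pchisqmix(2 * r$Q, 2 * r$lambda)$p, tolerance = 1e-9)
  # allele-label flips leave the test invariant (centering via projection)
  Mf <- M; Mf[, 2] <- 2L - Mf[, 2]
  rf <- gene_score_test(nf, Mf)
  expect_equal(rf$Q, r$Q, tolerance = 1e-9)
  expect_equal(rf$p, r$p, tolerance = 1e-7)
})

test_that("analytic p-values agree with resampling oracles on a toy gene", {
  set.seed(17)
  n <- 30
  y <- rnorm(n)
  M <- matrix(rbinom(n * 3, 2, c(0.08, 0.15, 0.05)), n, 3, byrow = TRUE)
  nf <- fit_null_model(y, kinship = diag(n))
  obs <- gene_score_test(nf, M)
  B <- 100000
  w <- nf$w[1]                      # identity kinship: equal weights
  Mc <- scale(M, center = TRUE, scale = FALSE)
  qstat <- function(yp) sum((crossprod(Mc, w * (yp - mean(yp))))^2)
  # parametric Monte Carlo under the fitted null, y* ~ N(0, V0): a sharp
  # check of the mixture-of-chi-squares machinery (3 Monte-Carlo SEs)
  set.seed(18)
  sd0 <- sqrt(nf$s2a + nf$s2e)
  q_mc <- replicate(B, qstat(rnorm(n, sd = sd0)))
  p_mc <- (1 + sum(q_mc >= obs$Q)) / (B + 1)
  expect_lt(abs(obs$p - p_mc), 3 * sqrt(p_mc * (1 - p_mc) / B))
  # permutation of y: conditions on the realized sample's higher moments,
  # so agreement is close but not within pure Monte-Carlo error at n = 30
  q_perm <- replicate(B, qstat(sample(y)))
  p_perm <- (1 + sum(q_perm >= obs$Q)) / (B + 1)
  expect_lt(abs(obs$p - p_perm), 0.01)
})

test_that("a causal gene outranks null genes in the scan", {
  map <- tiny_map(seed = 23, n_chr = 2, genes_per_chr = 10, rlfv_per_gene = 8,
                  n_common_per_chr = 5)
  pop <- tiny_pop(map, n_sires = 25, daughters_per_sire = 16, seed = 24)
  g <- offspring_geno(pop)
  v <- map$variants
  causal_gene <- "chr1_g3"
  qid <- v$id[v$gene %in% causal_gene & !is.na(v$gene)]
  set.seed(25)
  beta <- rnorm(length(qid), sd = 1)
  signal <- as.vector(g[, qid] %*% beta)
  signal <- signal / sd(signal) * 2
  y <- signal + rnorm(nrow(g))
  ph <- data.frame(id = rownames(g), y = y)
  A <- relmat_subset(pedigree_a_matrix(pop$pedigree), rownames(g))
  sc <- scan_genes(map, g, ph, A, alpha = 0.01)
  res <- sc$results
  expect_equal(nrow(res), 20)
  expect_lt(res$p[res$gene == causal_gene],
            median(res$p[res$gene != causal_gene]))
  expect_true(causal_gene %in% sc$mapped_genes)
  # mapped genes are exactly those below alpha
  expect_setequal(sc$mapped_genes,
                  res$gene[res$p < 0.01 & res$status == "ok"])
})

test_that("scan results are deterministic and sorted by p", {
  map <- tiny_map(seed = 33, n_chr = 2, genes_per_chr = 6, rlfv_per_gene = 5,
                  n_common_per_chr = 5)
  pop <- tiny_pop(map, n_sires = 10, daughters_per_sire = 8, seed = 34)
  g <- offspring_geno(pop)
  set.seed(35)
  ph <- data.frame(id = rownames(g), y = rnorm(nrow(g)))
  A <- relmat_subset(pedigree_a_matrix(pop$pedigree), rownames(g))
  s1 <- scan_genes(map, g, ph, A)
  s2 <- scan_genes(map, g, ph, A)
  expect_identical(s1$results, s2$results)
  expect_false(is.unsorted(s1$results$p))
})
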