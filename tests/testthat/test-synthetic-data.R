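test_that("genome map respects counts, MAF windows and determinism", {
  map <- simulate_genome_map(n_chr = 29, genes_per_chr = 10, rlfv_per_gene = 3,
                             n_common_per_chr = 10, seed = 7)
  expect_equal(nrow(map$genes), 290)
  v <- map$variants
  expect_true(all(v$target_maf[v$panel == "common_50k"] >= 0.05))
  rl <- v$target_maf[v$panel == "sequence_rlfv"]
  expect_true(all(rl >= 0.001 & rl < 0.05))
  # every RLFV belongs to exactly one gene, positions sorted within genes
  genic <- v[!is.na(v$gene), ]
  expect_equal(as.vector(table(genic$gene)[map$genes$gene_id]), rep(3L, 290))
  expect_true(all(tapply(genic$pos, genic$gene, function(p) !is.unsorted(p))))
  # determinism
  map2 <- simulate_genome_map(n_chr = 29, genes_per_chr = 10, rlfv_per_gene = 3,
                              n_common_per_chr = 10, seed = 7)
  expect_identical(map, map2)
  expect_error(simulate_genome_map(annotation_class_probs = c(high = 0.5, medium = 0.5, low = 0.5)),
               "sum to 1")
})

test_that("annotation classes are drawn at the configured probabilities", {
  # 10,000 RLFV; realized class counts must sit in the exact binomial 99% CI
  map <- simulate_genome_map(n_chr = 10, genes_per_chr = 50, rlfv_per_gene = 20,
                             n_common_per_chr = 1, seed = 11)
  cls <- map$variants$class[map$variants$panel == "sequence_rlfv"]
  expect_length(cls, 10000)
  probs <- c(high = 0.01, medium = 0.02, low = 0.97)
  for (k in names(probs)) {
    lo <- qbinom(0.005, 10000, probs[k])
    hi <- qbinom(0.995, 10000, probs[k])
    expect_gte(sum(cls == k), lo)
    expect_lte(sum(cls == k), hi)
  }
})

test_that("founder genotypes track target frequencies and are unrelated", {
  map <- tiny_map(seed = 5, n_chr = 2, genes_per_chr = 10, rlfv_per_gene = 5,
                  n_common_per_chr = 50)
  pop <- simulate_population(map, n_sires = 2000, daughters_per_sire = 0, seed = 9)
  expect_equal(nrow(pop$genotypes), 2000)
  p_hat <- colMeans(pop$genotypes) / 2
  p_tgt <- map$variants$target_maf
  se <- sqrt(p_tgt * (1 - p_tgt) / (2 * 2000))
  # ~99.7% of loci expected within 3 SE; require a conservative 95%
  expect_gte(mean(abs(p_hat - p_tgt) <= 3 * se), 0.95)
})

test_that("founder-only GRM is near-identity in expectation", {
  g <- random_dosages(100, 5000, seed = 31)
  G <- vanraden_grm(g)
  off <- G[upper.tri(G)]
  expect_lt(abs(mean(off)), 0.02)
  expect_lt(abs(mean(diag(G)) - 1), 0.05)
})

test_that("gene dropping yields half-sib relatives and unbiased frequencies", {
  map <- simulate_genome_map(n_chr = 4, genes_per_chr = 100, rlfv_per_gene = 10,
                             n_common_per_chr = 1500, seed = 13)
  pop <- simulate_population(map, n_sires = 30, daughters_per_sire = 10, seed = 14)
  ped <- pop$pedigree
  off <- ped$id[ped$generation == 1L]
  A <- pedigree_a_matrix(ped)
  # first two daughters share a sire, unrelated dams
  expect_equal(A[off[1], off[2]], 0.25)
  # daughters of different sires are unrelated
  expect_equal(A[off[1], off[11]], 0)
  # allele-count conservation over 10,000 loci: mean offspring-founder
  # frequency difference is 0 within 4 SE of the mean difference
  pf <- colMeans(pop$genotypes[ped$generation == 0L, ]) / 2
  po <- colMeans(pop$genotypes[off, ]) / 2
  d <- po - pf
  expect_length(d, 10000)
  expect_lt(abs(mean(d)), 4 * sd(d) / sqrt(length(d)))
})

test_that("DRP construction hits its variance targets and cohort split", {
  g <- random_dosages(800, 300, seed = 41)
  ph <- simulate_drp(g, sigma2_g = 145, total_variance = 328.8,
                     mean_r2_drp = 0.85, n_validation = 150, seed = 42)
  expect_equal(var(ph$tbv), 145, tolerance = 1e-10)
  expect_equal(sum(ph$cohort == "validation"), 150)
  # validation block is exactly the youngest 150 by birth rank
  expect_setequal(ph$id[ph$cohort == "validation"],
                  ph$id[order(ph$birth_rank, decreasing = TRUE)][1:150])
  expect_equal(mean(ph$r2_drp), 0.85, tolerance = 0.02)
  # observed DRP variance ~ sigma2_g / r2 under the reliability noise model
  expect_equal(var(ph$drp), 145 / 0.85, tolerance = 0.15 * 145 / 0.85)
  # perfect reliability means DRP record the TBV exactly
  ph1 <- simulate_drp(g, 145, 328.8, mean_r2_drp = 1, n_validation = 10, seed = 43)
  expect_identical(ph1$drp, ph1$tbv)
  expect_error(simulate_drp(g, 400, 328.8, 0.85, 10), "sigma2_g")
  expect_error(simulate_drp(g, 145, 328.8, 1.2, 10), "mean_r2_drp")
})

test_that("QTN scenarios select the documented gene counts and scale exactly", {
  map <- tiny_map(seed = 51, n_chr = 3, genes_per_chr = 12)
  pop <- tiny_pop(map, n_sires = 20, daughters_per_sire = 10, seed = 52)
  g <- offspring_geno(pop)
  q_l <- simulate_qtn_scenario(map, g, "LQTN", 0.10, 145, seed = 53)
  expect_length(q_l$genes, 9)
  q_m <- simulate_qtn_scenario(map, g, "MQTN", 0.10, 145, seed = 54)
  expect_length(q_m$genes, 3)  # one per chromosome
  q_s <- simulate_qtn_scenario(map, g, "SQTN", 0.10, 145, seed = 55)
  expect_true(q_s$genes_per_chr_drawn %in% 7:10)
  expect_length(q_s$genes, 3 * q_s$genes_per_chr_drawn)
  # exact variance scaling, relative error < 1e-10
  expect_equal(var(q_l$tbv_q), 0.10 * 145, tolerance = 1e-10)
  expect_equal(q_l$realized_var, 14.5, tolerance = 1e-10)
  # the QTN set is the union of all RLFV in the selected genes
  v <- map$variants
  expect_setequal(q_l$qtn_ids, v$id[!is.na(v$gene) & v$gene %in% q_l$genes])
  expect_error(simulate_qtn_scenario(map, g, "LQTN", 0, 145), "fraction")
  # monomorphic genes cannot carry a scalable QTN set
  g0 <- g; g0[] <- 0L
  expect_error(simulate_qtn_scenario(map, g0, "LQTN", 0.1, 145, seed = 53),
               "monomorphic")
})

test_that("phenotype composition adds the overlay and decomposes variance", {
  map <- tiny_map(seed = 61, n_chr = 2, genes_per_chr = 10)
  pop <- simulate_population(map, n_sires = 600, daughters_per_sire = 0, seed = 62)
  g <- pop$genotypes
  cid <- map$variants$id[map$variants$panel == "common_50k"]
  ph <- simulate_drp(g[, cid], 145, 328.8, 0.85, n_validation = 100, seed = 63)
  q <- simulate_qtn_scenario(map, g, "LQTN", 0.10, 145, seed = 64)
  ph2 <- compose_phenotype(ph, q)
  expect_equal(ph2$y, ph$drp + unname(q$tbv_q[ph$id]))
  expect_identical(ph2[setdiff(names(ph2), "y")], ph[setdiff(names(ph), "y")])
  # founders: QTN genes are independent of the common polygenic panel
  expect_equal(var(ph2$y), var(ph$drp) + var(q$tbv_q),
               tolerance = 0.15 * var(ph$drp))
  bad <- ph; bad$id <- paste0("x", bad$id)
  expect_error(compose_phenotype(bad, q), "IDs")
})

test_that("simulation is bitwise reproducible for a fixed seed", {
  map <- tiny_map(seed = 71)
  p1 <- simulate_population(map, 5, 4, seed = 72)
  p2 <- simulate_population(map, 5, 4, seed = 72)
  expect_identical(p1, p2)
  g <- offspring_geno(p1)
  cid <- map$variants$id[map$variants$panel == "common_50k"]
  expect_identical(simulate_drp(g[, cid], 145, 328.8, 0.85, 5, seed = 73),
                   simulate_drp(g[, cid], 145, 328.8, 0.85, 5, seed = 73))
  expect_identical(simulate_qtn_scenario(map, g, "SQTN", 0.1, 145, seed = 74),
                   simulate_qtn_scenario(map, g, "SQTN", 0.1, 145, seed = 74))
})
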