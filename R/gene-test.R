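#' Survival function of a positive linear combination of chi-squares
#'
#' Computes `P(Q > q)` for `Q = sum_k lambda_k chi2_1` by numerical
#' inversion of the characteristic function (Imhof's integral, evaluated
#' with adaptive quadrature). When the quadrature fails to converge, a
#' Satterthwaite moment-matching approximation (`Q ~ a * chi2_nu` with `a =
#' sum(lambda^2)/sum(lambda)`, `nu = sum(lambda)^2/sum(lambda^2)`) is used
#' and reported in the `method` field.
#'
#' @param q observed statistic (scalar, >= 0).
#' @param lambda positive mixture weights (eigenvalues).
#' @return list with `p` (in (0, 1\]) and `method` (`"imhof"` or
#'   `"satterthwaite"`).
#' @export
pchisqmix <- function(q, lambda) {
  lambda <- lambda[lambda > 0]
  if (length(lambda) == 0 || q <= 0) return(list(p = 1, method = "degenerate"))
  # Imhof's integrand on (0, Inf), mapped to t in (0, pi/2) via u = tan(t)
  # so adaptive quadrature works on a finite interval
  integrand <- function(t) {
    vapply(t, function(ti) {
      ui <- tan(ti)
      if (!is.finite(ui) || ui <= 0) return(0)
      th <- 0.5 * sum(atan(lambda * ui)) - 0.5 * q * ui
      rho <- exp(0.25 * sum(log1p((lambda * ui)^2)))
      sin(th) / (ui * rho) * (1 + ui^2)
    }, numeric(1))
  }
  res <- NULL
  for (rel_tol in c(1e-8, 1e-6)) {
    res <- tryCatch(
      stats::integrate(integrand, lower = 0, upper = pi / 2,
                       rel.tol = rel_tol, abs.tol = 1e-12, subdivisions = 5000L,
                       stop.on.error = TRUE),
      error = function(e) NULL
    )
    if (!is.null(res)) break
  }
  satterthwaite <- function() {
    a <- sum(lambda^2) / sum(lambda)
    nu <- sum(lambda)^2 / sum(lambda^2)
    list(p = stats::pchisq(q / a, df = nu, lower.tail = FALSE),
         method = "satterthwaite")
  }
  if (is.null(res)) return(satterthwaite())
  p <- 0.5 + res$value / pi
  if (!is.finite(p) || p < -1e-6 || p > 1 + 1e-6) return(satterthwaite())
  list(p = min(max(p, .Machine$double.xmin), 1), method = "imhof")
}

#' Fit the polygenic null model for gene-level association scans
#'
#' Fits `y = X gamma + u + e` with `u ~ N(0, A s2_a)` by REML (delegating to
#' [reml_fit()]'s spectral path) and caches the pieces of the null
#' covariance `V0 = A s2_a + I s2_e` needed by the score test: the
#' eigen-rotation of the kinship, the generalized-least-squares covariate
#' solution and the null residual `r = V0^-1 (y - X gamma_hat)`. The null
#' model is fitted once per trait and reused across all genes.
#'
#' @param y phenotypes of the (training) individuals.
#' @param covariates optional numeric matrix of covariates (an intercept is
#'   always included).
#' @param kinship n x n relationship matrix aligned with `y` (pedigree `A`
#'   by design; a GRM is accepted).
#' @return object of class `null_model` caching the REML fit and the
#'   factorization used by [gene_score_test()].
#' @export
fit_null_model <- function(y, covariates = NULL, kinship) {
  n <- length(y)
  X <- if (is.null(covariates)) matrix(1, n, 1) else cbind(1, as.matrix(covariates))
  colnames(X)[1] <- "(Intercept)"
  K <- unclass(kinship)
  stopifnot(is.matrix(K), nrow(K) == n, ncol(K) == n)
  fit <- reml_fit(y, list(a = K), X = X)
  s2a <- fit$varcomp[["a"]]
  s2e <- fit$varcomp[["residual"]]
  E <- eigen(K, symmetric = TRUE)
  d <- pmax(E$values, 0)
  U <- E$vectors
  w <- 1 / (s2a * d + s2e)
  yt <- as.vector(crossprod(U, y))
  Xt <- crossprod(U, X)
  Wx <- Xt * w
  XtWX_inv <- solve(crossprod(Xt, Wx))
  gamma <- as.vector(XtWX_inv %*% crossprod(Wx, yt))
  r_rot <- w * (yt - as.vector(Xt %*% gamma))
  structure(list(fit = fit, U = U, d = d, w = w, Xt = Xt, Wx = Wx,
                 XtWX_inv = XtWX_inv, gamma = gamma, r_rot = r_rot,
                 s2a = s2a, s2e = s2e, n = n),
            class = "null_model")
}

#' @export
print.null_model <- function(x, ...) {
  cat(sprintf("null_model: s2_a = %.4g, s2_e = %.4g (n = %d)\n",
              x$s2a, x$s2e, x$n))
  invisible(x)
}

# score test from a pre-rotated dosage matrix Mt = U'M
.score_from_rotated <- function(nf, Mt) {
  qstat <- sum(as.vector(crossprod(Mt, nf$r_rot))^2)
  WM <- Mt * nf$w
  B <- crossprod(Mt, WM) -
    crossprod(Mt, nf$Wx) %*% nf$XtWX_inv %*% crossprod(nf$Wx, Mt)
  lam <- eigen((B + t(B)) / 2, symmetric = TRUE, only.values = TRUE)$values
  lam <- lam[lam > max(lam, 0) * 1e-10 & lam > 1e-12]
  if (length(lam) == 0) {
    return(list(Q = qstat, p = 1, status = "degenerate", method = "degenerate",
                lambda = numeric(0)))
  }
  pv <- pchisqmix(qstat, lam)
  list(Q = qstat, p = pv$p, status = "ok", method = pv$method, lambda = lam)
}

#' Variance-component score test for one gene's rare variants
#'
#' famSKAT-style kernel test: the `m` genic variants enter as random
#' effects with a common variance and equal weights, and the score
#' statistic `Q = r' M M' r` with `r = V0^-1 (y - X gamma_hat)` is referred
#' to its null distribution, a mixture of chi-squares with weights equal to
#' the eigenvalues of `M' P0 M` (`P0` the null REML projection). No
#' assumption is made about the direction of the variant effects.
#'
#' @param null_fit a `null_model` from [fit_null_model()].
#' @param M dosage matrix (individuals x variants of one gene), rows
#'   aligned with the null-model individuals.
#' @return list of class `gene_test`: `n_variants`, `Q`, `p`, `status`
#'   (`"ok"` or `"degenerate"`, the latter when all gene variants are
#'   monomorphic in sample), `method`, `lambda`.
#' @export
gene_score_test <- function(null_fit, M) {
  stopifnot(inherits(null_fit, "null_model"))
  M <- as.matrix(M)
  storage.mode(M) <- "double"
  if (nrow(M) != null_fit$n) stop("gene dosage rows do not match the null-model individuals")
  out <- .score_from_rotated(null_fit, crossprod(null_fit$U, M))
  out$n_variants <- ncol(M)
  class(out) <- "gene_test"
  out
}

#' Gene-by-gene rare-variant association scan
#'
#' Fits the polygenic null model once on the training individuals, then
#' score-tests the RLFV set of every gene in the map. Genes with `p <
#' alpha` (strict) are returned as mapped genes.
#'
#' @param genome_map a `genome_map`.
#' @param genotypes dosage matrix covering the training individuals (rows
#'   by ID) and the genic RLFV (columns by variant ID).
#' @param phenotypes_training phenotype data.frame (columns `id`, `y`) of
#'   the training cohort only.
#' @param kinship relationship matrix covering (at least) the training
#'   individuals, with dimnames.
#' @param alpha significance threshold in (0, 1); default 0.01.
#' @return list with `mapped_genes` (character vector) and `results`
#'   (data.frame sorted by p: `gene`, `n_variants`, `Q`, `p`, `status`,
#'   `method`).
#' @export
scan_genes <- function(genome_map, genotypes, phenotypes_training, kinship,
                       alpha = 0.01) {
  stopifnot(inherits(genome_map, "genome_map"))
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0, 1)")
  ids <- phenotypes_training$id
  gi <- match(ids, rownames(genotypes))
  if (anyNA(gi)) stop("training individuals missing from genotypes")
  K <- unclass(kinship)
  ki <- match(ids, rownames(K))
  if (anyNA(ki)) stop("training individuals missing from kinship")
  nf <- fit_null_model(phenotypes_training$y, kinship = K[ki, ki, drop = FALSE])

  v <- genome_map$variants
  genic <- !is.na(v$gene) & v$id %in% colnames(genotypes)
  if (!any(genic)) stop("no genes with genotyped RLFV")
  vg <- v[genic, , drop = FALSE]
  M_all <- genotypes[gi, vg$id, drop = FALSE]
  storage.mode(M_all) <- "double"
  Mt_all <- crossprod(nf$U, M_all)
  cols_by_gene <- split(seq_len(ncol(Mt_all)), vg$gene)
  res <- lapply(names(cols_by_gene), function(g) {
    st <- .score_from_rotated(nf, Mt_all[, cols_by_gene[[g]], drop = FALSE])
    data.frame(gene = g, n_variants = length(cols_by_gene[[g]]),
               Q = st$Q, p = st$p, status = st$status, method = st$method,
               stringsAsFactors = FALSE)
  })
  results <- do.call(rbind, res)
  results <- results[order(results$p, results$gene), , drop = FALSE]
  rownames(results) <- NULL
  mapped <- results$gene[results$status == "ok" & results$p < alpha]
  list(mapped_genes = mapped, results = results, null_model = nf)
}
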