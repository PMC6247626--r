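#' Observed allele frequencies of the counted allele
#'
#' @param genotypes dosage matrix (individuals x variants, values 0/1/2 of
#'   the counted allele).
#' @param variant_subset optional column selector (indices, names or a
#'   `variant_subset` object); default all columns.
#' @return named numeric vector `p` with `p_j = mean(dosage_j) / 2`.
#' @export
allele_frequencies <- function(genotypes, variant_subset = NULL) {
  j <- .resolve_variants(genotypes, variant_subset)
  if (length(j) == 0) stop("variant subset is empty")
  colMeans(genotypes[, j, drop = FALSE]) / 2
}

# accept indices, variant IDs, or a variant_subset object
.resolve_variants <- function(genotypes, variant_subset) {
  if (is.null(variant_subset)) return(seq_len(ncol(genotypes)))
  if (inherits(variant_subset, "variant_subset")) variant_subset <- variant_subset$ids
  if (is.character(variant_subset)) {
    j <- match(variant_subset, colnames(genotypes))
    if (anyNA(j)) stop("unknown variant IDs in subset")
    return(j)
  }
  as.integer(variant_subset)
}

#' Genomic relationship matrix, VanRaden method 1
#'
#' Computes `G = (X - 2p1')(X - 2p1')' / (2 * sum_j p_j (1 - p_j))` where `X`
#' holds allele dosages of the counted allele and `p` the allele
#' frequencies. The denominator scales `G` to be comparable to the
#' pedigree-based additive relationship matrix. Monomorphic variants have
#' zero centered dosage and zero `p(1-p)`, so they contribute to neither
#' numerator nor denominator.
#'
#' @inheritParams allele_frequencies
#' @param freqs optional allele frequencies of the counted allele; if
#'   omitted they are computed from `genotypes` itself.
#' @return an n x n `relmat` (dense symmetric matrix with attributes `kind =
#'   "genomic"`, `denom` and `p`).
#' @export
vanraden_grm <- function(genotypes, variant_subset = NULL, freqs = NULL) {
  j <- .resolve_variants(genotypes, variant_subset)
  if (length(j) == 0) stop("variant subset is empty")
  X <- genotypes[, j, drop = FALSE]
  storage.mode(X) <- "double"
  p <- if (is.null(freqs)) colMeans(X) / 2 else as.numeric(freqs)
  if (length(p) != ncol(X)) stop("freqs length does not match subset")
  denom <- 2 * sum(p * (1 - p))
  if (!(denom > 0)) stop("all variants in subset are monomorphic (zero denominator)")
  W <- sweep(X, 2L, 2 * p, check.margin = FALSE)
  G <- tcrossprod(W) / denom
  G <- (G + t(G)) / 2
  structure(G, kind = "genomic", denom = denom, p = p, class = c("relmat", "matrix"))
}

#' Stabilize a genomic relationship matrix for dense solves
#'
#' Adds `jitter` to the diagonal when the smallest eigenvalue is below
#' `-tol`. GRMs built as centered cross-products are positive semi-definite
#' up to rounding, so this is rarely triggered; it guards rank-deficient
#' matrices built from very few rare variants.
#'
#' @param G a `relmat` of genomic kind.
#' @param tol eigenvalue tolerance.
#' @param jitter diagonal boost applied when needed.
#' @return `G`, possibly with a boosted diagonal.
#' @export
stabilize_relmat <- function(G, tol = 1e-8, jitter = 1e-6) {
  ev_min <- min(eigen(unclass(G), symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min < -tol) {
    diag(G) <- diag(G) + jitter
  }
  G
}

#' Pedigree-based additive relationship matrix (tabular method)
#'
#' Builds `A` by the recursive tabular method: `a_ij = (a_{sire(i),j} +
#' a_{dam(i),j}) / 2` for `j < i` and `a_ii = 1 + a_{sire(i),dam(i)} / 2`,
#' with unknown parents contributing zero. Founders are assumed unrelated
#' and non-inbred. Parents must be listed before their offspring.
#'
#' @param pedigree data.frame with columns `id`, `sire`, `dam` (`NA` =
#'   unknown), ordered so parents precede offspring.
#' @return an n x n `relmat` with attribute `kind = "pedigree"` and
#'   dimnames from `pedigree$id`.
#' @export
pedigree_a_matrix <- function(pedigree) {
  stopifnot(all(c("id", "sire", "dam") %in% names(pedigree)))
  ids <- pedigree$id
  n <- length(ids)
  if (anyDuplicated(ids)) stop("duplicated individual IDs in pedigree")
  si <- match(pedigree$sire, ids)
  di <- match(pedigree$dam, ids)
  known_s <- !is.na(pedigree$sire)
  known_d <- !is.na(pedigree$dam)
  if (any(known_s & is.na(si)) || any(known_d & is.na(di)))
    stop("parent IDs missing from pedigree")
  if (any(si >= seq_len(n), na.rm = TRUE) || any(di >= seq_len(n), na.rm = TRUE))
    stop("pedigree not sorted: an individual appears at or before its parent (or is its own ancestor)")
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    if (i > 1L) {
      jj <- seq_len(i - 1L)
      row <- 0.5 * ((if (is.na(s)) 0 else A[s, jj]) + (if (is.na(d)) 0 else A[d, jj]))
      A[i, jj] <- row
      A[jj, i] <- row
    }
    A[i, i] <- 1 + if (is.na(s) || is.na(d)) 0 else 0.5 * A[s, d]
  }
  structure(A, kind = "pedigree", class = c("relmat", "matrix"))
}

#' @export
print.relmat <- function(x, ...) {
  cat(sprintf("relmat [%s]: %d x %d, mean diagonal %.3f\n",
              attr(x, "kind"), nrow(x), ncol(x), mean(diag(x))))
  invisible(x)
}

#' Subset a relationship matrix to a set of individuals
#'
#' @param x a `relmat`.
#' @param ids individual IDs (must be present in the dimnames).
#' @return the `relmat` restricted to `ids`, attributes preserved.
#' @export
relmat_subset <- function(x, ids) {
  i <- match(ids, rownames(x))
  if (anyNA(i)) stop("unknown individual IDs")
  out <- unclass(x)[i, i, drop = FALSE]
  structure(out, kind = attr(x, "kind"), denom = attr(x, "denom"),
            p = attr(x, "p"), class = c("relmat", "matrix"))
}
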