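#' @title RLFV subset selection
#' @description Constructors of the variant subsets used to build the second
#'   genomic relationship matrix: the MAF window, genic restriction,
#'   annotation classes, mapped genes and random matched controls. All
#'   selections operate on observed sample allele frequencies and return a
#'   `variant_subset` carrying its provenance.
#' @name selection
NULL

.variant_subset <- function(ids, label, strategy, params = list(), seed = NA) {
  ids <- unique(as.character(ids))
  structure(list(label = label, ids = ids, strategy = strategy,
                 params = params, seed = seed, count = length(ids)),
            class = "variant_subset")
}

#' @export
print.variant_subset <- function(x, ...) {
  cat(sprintf("variant_subset '%s' (%s): %d variants\n", x$label, x$strategy, x$count))
  invisible(x)
}

#' Filter variants to a minor-allele-frequency window
#'
#' Keeps variants with `maf_floor <= MAF < maf_ceiling`, where MAF is
#' `min(p, 1-p)` of the observed sample allele frequency. The floor is
#' inclusive and the ceiling exclusive: rare and low-frequency variants
#' (RLFV) are those with MAF below 0.05, and variants below MAF 0.001 are
#' discarded. On the full sample the floor corresponds to a minimum
#' minor-allele copy count (see [maf_copy_threshold()]).
#'
#' @param genotypes dosage matrix over the full genotyped sample.
#' @param maf_floor,maf_ceiling window bounds, `0 <= floor < ceiling <= 0.5`.
#' @return a `variant_subset` labelled `"rlfv"`.
#' @export
filter_rlfv <- function(genotypes, maf_floor = 0.001, maf_ceiling = 0.05) {
  if (!(maf_floor >= 0 && maf_floor < maf_ceiling && maf_ceiling <= 0.5))
    stop("need 0 <= maf_floor < maf_ceiling <= 0.5")
  p <- colMeans(genotypes) / 2
  maf <- pmin(p, 1 - p)
  keep <- maf >= maf_floor & maf < maf_ceiling
  if (!any(keep)) warning("MAF window selected no variants")
  .variant_subset(colnames(genotypes)[keep], "rlfv", "maf_window",
                  params = list(maf_floor = maf_floor, maf_ceiling = maf_ceiling))
}

#' Minimum minor-allele copies implied by a MAF floor
#'
#' The smallest minor-allele copy count that passes `MAF >= maf_floor` in a
#' diploid sample: `ceiling(maf_floor * 2 * n_individuals)`. With 6337
#' individuals and a floor of 0.001 this is 13 copies.
#'
#' @param n_individuals number of diploid individuals.
#' @param maf_floor the MAF floor.
#' @return integer copy count.
#' @export
maf_copy_threshold <- function(n_individuals, maf_floor = 0.001) {
  as.integer(ceiling(maf_floor * 2 * n_individuals))
}

#' Restrict a subset to genic variants
#'
#' @param subset a `variant_subset`.
#' @param genome_map a `genome_map`.
#' @return a `variant_subset` of the members assigned to any gene.
#' @export
select_genic <- function(subset, genome_map) {
  v <- genome_map$variants
  genic_ids <- v$id[!is.na(v$gene)]
  if (length(genic_ids) == 0) warning("genome map contains no genes")
  .variant_subset(intersect(subset$ids, genic_ids), "all_genic", "genic")
}

#' Restrict a subset by annotation class
#'
#' `classes = "high"` selects high-impact RLFV only; `classes = c("high",
#' "medium")` the medium-to-high union.
#'
#' @param subset a `variant_subset`.
#' @param genome_map a `genome_map`.
#' @param classes non-empty subset of `c("high", "medium")`.
#' @return a `variant_subset`.
#' @export
select_by_annotation <- function(subset, genome_map, classes) {
  if (length(classes) == 0) stop("classes must be non-empty")
  if (!all(classes %in% c("high", "medium")))
    stop("unknown annotation class; allowed: 'high', 'medium'")
  v <- genome_map$variants
  keep <- v$id[v$class %in% classes & !is.na(v$gene)]
  .variant_subset(intersect(subset$ids, keep),
                  paste0("annotation_", paste(sort(classes), collapse = "_")),
                  "annotation", params = list(classes = classes))
}

#' Restrict a subset to RLFV of mapped genes
#'
#' @param subset a `variant_subset`.
#' @param genome_map a `genome_map`.
#' @param mapped_genes character vector of gene IDs (typically the `p <
#'   0.01` genes from [scan_genes()]).
#' @return a `variant_subset`.
#' @export
select_by_mapping <- function(subset, genome_map, mapped_genes) {
  v <- genome_map$variants
  keep <- v$id[!is.na(v$gene) & v$gene %in% mapped_genes]
  .variant_subset(intersect(subset$ids, keep), "mapped", "mapping",
                  params = list(n_genes = length(mapped_genes)))
}

#' Draw a random matched control subset
#'
#' Uniform sample without replacement of `target_count` members, the control
#' for "is it the specific variants, or just their number, that matters".
#'
#' @param subset a `variant_subset`.
#' @param target_count number of variants to draw, `<= subset$count`.
#' @param seed integer seed (sampling is deterministic per seed).
#' @return a `variant_subset`.
#' @export
select_random_matched <- function(subset, target_count, seed = 1) {
  if (target_count > subset$count) stop("target_count exceeds subset size")
  set.seed(as.integer(seed))
  ids <- if (target_count == 0) character(0) else sample(subset$ids, target_count)
  .variant_subset(ids, "random_matched", "random",
                  params = list(target_count = target_count), seed = seed)
}
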