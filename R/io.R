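#' @title File interfaces
#' @description Readers and writers for the standard exchange formats:
#'   genotypes as VCF (GT fields, one contig per chromosome) or PLINK-style
#'   dosage TSV, gene maps as BED (0-based half-open) plus an annotation
#'   TSV, phenotypes and pedigrees as TSV, variant subsets as an ID list
#'   with a JSON provenance sidecar, and experiment configurations as YAML.
#' @name io
NULL

#' Write genotypes as a VCF file
#'
#' Emits a minimal VCFv4.2 with one contig line per chromosome and phased
#' GT genotypes consistent with the dosage of the ALT (counted) allele.
#' Heterozygotes are written as `0|1`.
#'
#' @param genotypes dosage matrix (individuals x variants).
#' @param genome_map the `genome_map` describing the variant columns.
#' @param path output path (plain text).
#' @return `path`, invisibly.
#' @export
write_genotypes_vcf <- function(genotypes, genome_map, path) {
  v <- genome_map$variants[match(colnames(genotypes), genome_map$variants$id), , drop = FALSE]
  if (anyNA(v$id)) stop("genotype columns missing from genome map")
  gt_codes <- c("0|0", "0|1", "1|1")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               sprintf("##contig=<ID=%s>", unique(v$chr)),
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">"), con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", rownames(genotypes)), collapse = "\t"), con)
  gt <- matrix(gt_codes[t(genotypes) + 1L], nrow = ncol(genotypes))
  body <- cbind(v$chr, v$pos, v$id, "A", "C", ".", "PASS", ".", "GT", gt)
  writeLines(apply(body, 1L, paste, collapse = "\t"), con)
  invisible(path)
}

#' Read allele dosages from a VCF file
#'
#' Parses GT fields with `vcfR` and returns the dosage of the ALT allele.
#'
#' @param path a VCF file.
#' @return integer dosage matrix, individuals x variants.
#' @export
read_genotypes_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the 'vcfR' package")
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  dose <- matrix(0L, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  dose[] <- vapply(strsplit(gsub("\\|", "/", gt), "/"),
                   function(a) sum(a != "0"), integer(1))
  t(dose)
}

#' Write genotypes as a PLINK-style dosage TSV
#'
#' Individuals in rows (`id` column first), one column per variant.
#'
#' @inheritParams write_genotypes_vcf
#' @export
write_dosage_tsv <- function(genotypes, path) {
  dt <- data.table::as.data.table(genotypes, keep.rownames = "id")
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' @rdname write_dosage_tsv
#' @param path file path.
#' @return for the reader, an integer dosage matrix with individual IDs as
#'   rownames.
#' @export
read_dosage_tsv <- function(path) {
  dt <- data.table::fread(path, sep = "\t")
  ids <- dt[[1]]
  m <- as.matrix(dt[, -1])
  storage.mode(m) <- "integer"
  rownames(m) <- ids
  m
}

#' Write a gene map as BED plus an annotation TSV
#'
#' The BED file (0-based, half-open) holds one interval per gene with the
#' gene ID in the name column, written through `rtracklayer`. The companion
#' TSV (`<path>.annotation.tsv`) holds the per-variant positions,
#' annotation classes and panel flags.
#'
#' @param genome_map a `genome_map`.
#' @param bed_path output BED path.
#' @return `bed_path`, invisibly.
#' @export
write_genome_bed <- function(genome_map, bed_path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE) ||
      !requireNamespace("GenomicRanges", quietly = TRUE))
    stop("writing BED requires 'rtracklayer' and 'GenomicRanges'")
  g <- genome_map$genes
  gr <- GenomicRanges::GRanges(g$chr, IRanges::IRanges(g$start + 1L, g$end),
                               name = g$gene_id)
  rtracklayer::export(gr, bed_path, format = "BED")
  data.table::fwrite(genome_map$variants,
                     paste0(bed_path, ".annotation.tsv"), sep = "\t")
  invisible(bed_path)
}

#' Read a gene map written by [write_genome_bed()]
#'
#' @param bed_path the BED path (its `.annotation.tsv` sidecar must exist).
#' @return a `genome_map`.
#' @export
read_genome_bed <- function(bed_path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("reading BED requires 'rtracklayer'")
  gr <- rtracklayer::import(bed_path, format = "BED")
  variants <- as.data.frame(data.table::fread(paste0(bed_path, ".annotation.tsv"),
                                              sep = "\t", na.strings = c("NA", "")))
  genes <- data.frame(gene_id = gr$name,
                      chr = as.character(GenomicRanges::seqnames(gr)),
                      start = GenomicRanges::start(gr) - 1L,
                      end = GenomicRanges::end(gr),
                      stringsAsFactors = FALSE)
  genes$n_rlfv <- as.integer(table(variants$gene)[genes$gene_id])
  structure(list(chromosomes = unique(variants$chr), genes = genes,
                 variants = variants),
            class = "genome_map")
}

#' Write / read phenotype and pedigree tables as TSV
#'
#' @param x a data.frame (phenotypes or pedigree).
#' @param path file path.
#' @return the writer returns `path` invisibly; the reader a data.frame.
#' @export
write_table_tsv <- function(x, path) {
  data.table::fwrite(x, path, sep = "\t", na = "NA")
  invisible(path)
}

#' @rdname write_table_tsv
#' @export
read_table_tsv <- function(path) {
  as.data.frame(data.table::fread(path, sep = "\t", na.strings = "NA"))
}

#' Serialize a variant subset
#'
#' Writes the variant IDs as a one-column TSV and the provenance (label,
#' strategy, parameters, seed, count) as a JSON sidecar (`<path>.json`).
#'
#' @param subset a `variant_subset`.
#' @param path TSV path.
#' @return `path`, invisibly.
#' @export
write_variant_subset <- function(subset, path) {
  stopifnot(inherits(subset, "variant_subset"))
  data.table::fwrite(data.table::data.table(variant_id = subset$ids), path, sep = "\t")
  prov <- subset[c("label", "strategy", "params", "seed", "count")]
  jsonlite::write_json(prov, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_variant_subset
#' @export
read_variant_subset <- function(path) {
  ids <- data.table::fread(path, sep = "\t")$variant_id
  prov <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  .variant_subset(ids, prov$label, prov$strategy,
                  params = as.list(prov$params),
                  seed = if (is.null(prov$seed)) NA else prov$seed)
}

#' Load / save an experiment configuration as YAML
#'
#' @param path YAML file path.
#' @return `load_config` returns an `experiment_config`;
#'   `save_config` returns `path` invisibly.
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$annotation_class_probs <- unlist(raw$annotation_class_probs)
  do.call(default_config, c(list(seed = raw$seed %||% 1L),
                            raw[setdiff(names(raw), "seed")]))
}

#' @rdname load_config
#' @param config an `experiment_config`.
#' @export
save_config <- function(config, path) {
  cfg <- unclass(config)
  cfg$annotation_class_probs <- as.list(cfg$annotation_class_probs)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
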