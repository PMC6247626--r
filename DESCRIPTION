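Package: rlfvgp
Title: Genomic Prediction with Rare and Low-Frequency Sequence Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for studying how rare and
    low-frequency genic variants (RLFV) affect the reliability of genomic
    prediction in dairy-cattle-like populations. Simulates half-sib
    structured genotypes, de-regressed proofs (DRP) and causal rare-variant
    (QTN) scenarios; builds VanRaden method-1 genomic and pedigree-based
    additive relationship matrices; fits one- and two-component GBLUP models
    by restricted maximum likelihood (REML); selects RLFV subsets by
    minor-allele-frequency windows, annotation class, gene-level
    kernel-association mapping (famSKAT-style score test) or random matched
    sampling; and evaluates validation reliability, accuracy standard error
    and bias of genomic breeding values across replicated experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    GenomicRanges,
    IRanges,
    rtracklayer,
    S4Vectors,
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
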