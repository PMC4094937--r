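Package: twinmeth
Title: Twin Correlation Analysis of Genome-Wide DNA Methylation Arrays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested workflow for monozygotic-twin DNA methylation studies
    on Illumina 450k-style arrays, from per-probe signal intensities through
    probe and sample quality control, quantile normalization, beta- and
    M-value computation, beta-mixture quantile (BMIQ) harmonization of the
    two probe chemistries, and genomic-context annotation (gene-centric
    regions, CpG-island shores and shelves, regulatory and imprinted-region
    overlaps) to per-pair and per-CpG Spearman twin correlations stratified
    by genomic context. Includes a synthetic-data generator that emulates a
    twin study design (twin pairs plus replicated control DNA) with known
    familial and individual variance components, so every stage of the
    pipeline can be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    tools,
    limma,
    IRanges,
    S4Vectors,
    ape,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
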