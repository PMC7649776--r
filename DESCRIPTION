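Package: spaceqtl
Title: Spatial eQTL Mapping and Cross-Phenotype Regulatory Sharing via Hi-C
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps phenotype-associated SNPs to putative target genes through
    restriction-fragment Hi-C chromatin contacts, calls significant
    tissue-specific eQTL-eGene pairs with pooled Benjamini-Hochberg FDR
    control, and quantifies cross-phenotype sharing of eQTLs, eGenes and
    pathways with a resampling (bootstrap) null. Includes in-silico
    restriction digestion, Hi-C contact QC and capture, a brain-specific
    sub-analysis, hypergeometric pathway over-representation, drug-gene
    interaction joining, tissue-correlation diagnostics, and a synthetic-data
    generator with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
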