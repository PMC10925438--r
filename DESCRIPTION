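Package: dmrpipe
Title: Differential Methylation Region Calling and Expression Integration
    for Tumor Methylomes
Version: 1.0.0
Authors@R:
    person("Maren", "Kowalski", email = "mkowalski@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for whole-genome bisulfite sequencing (WGBS)
    differential methylation analysis of tumors against a panel of normal
    controls, with RNA-seq integration. Implements per-CpG differential
    methylation calling against an averaged control profile, rule-based
    segmentation of consecutive differentially methylated cytosines into
    regions tested with a Mann-Whitney U rank test, annotation of regions
    to genomic elements, cross-tumor recurrence signatures, simplified
    negative-binomial differential expression, and promoter-methylation by
    gene-expression integration. Ships a synthetic methylome and expression
    simulator with planted truth for end-to-end validation.
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
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
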