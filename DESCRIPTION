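Package: methdisrupt
Title: Methylation Disruption Analysis for Two-Color CpG Microarrays
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: End-to-end analysis of two-color CpG methylation-enrichment
    microarrays in a tumor-versus-control design: loess dye-bias correction,
    quantile normalization, probe-to-sequence median aggregation and
    low-methylation filtering; differential methylation (Mann-Whitney with
    Bonferroni control), differential variability (F-test), clinical-covariate
    regression and genomic-location enrichment; PCA-guided sequence selection
    with Ward hierarchical clustering for epigenetic subtyping and survival
    read-outs; and methylation-disruption analysis via per-sample methylation
    variability profiles (kernel density curves of differential methylation),
    an L1 area distance between profiles, methylation variability scores, and
    consensus clustering over MAD-ranked variable sequences. Includes a
    synthetic-data generator emulating the study design with planted ground
    truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3),
    SummarizedExperiment
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    limma,
    matrixStats,
    data.table,
    survival,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
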