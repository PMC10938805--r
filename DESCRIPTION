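Package: stageomics
Title: Stage-Series Multi-Omics Integration for Developing Fruit
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Integration of metabolome, proteome, transcriptome, whole-genome
    bisulfite and small-RNA data across an 11-stage developmental series.
    Provides stage-pairwise differential calling (fold-change and
    Benjamini-Hochberg FDR gates), z-score trend clustering of metabolites
    into eight archetypal clusters, construction of a gene-metabolite
    association database from Pearson correlations of stage means with a
    transcript/translation consistency filter, windowed differentially
    methylated region (DMR) calling in CG/CHG/CHH contexts with
    promoter-methylation coupling, metagene methylation profiles, 24-nt
    siRNA abundance normalization, adjacent-stage transition accounting,
    and a fully synthetic multi-omics generator with planted ground truth
    for end-to-end recovery benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    jsonlite,
    yaml,
    igraph,
    mclust,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
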