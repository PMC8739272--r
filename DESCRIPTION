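Package: ascmature
Title: Multi-Omic Analysis of Antibody-Secreting Cell Maturation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Statistical pipeline for comparing blood antibody-secreting
    cells with bone-marrow plasma-cell subsets across transcriptome,
    chromatin accessibility, B-cell receptor repertoire and morphometry
    readouts. Provides per-gene linear mixed-effects ANOVA with
    Tukey-Kramer pairwise contrasts and Benjamini-Hochberg correction,
    negative-binomial exact tests for differential peak accessibility,
    peak-to-gene assignment and expression/accessibility concordance
    classification, hypergeometric gene-set over-representation, gene-set
    z-score trajectories, Poisson and mixed-model morphometry statistics,
    clonal lineage assignment from AIRR rearrangement tables with Simpson
    diversity and longitudinal clone persistence, and seed-stable
    synthetic multi-omic and repertoire generators with planted ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    Biostrings,
    fgsea
Suggests:
    testthat (>= 3.0.0),
    lme4,
    edgeR,
    DESeq2,
    vegan,
    jsonlite
Config/testthat/edition: 3
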