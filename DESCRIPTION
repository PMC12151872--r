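Package: longescreen
Title: Expression-Based Screening for Longevity Genes and Lifespan
    Analysis Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An analysis toolkit for nominating essential longevity genes
    from a gene-deletion expression compendium joined to replicative
    lifespan phenotypes, and for characterising the transcriptional
    consequences of knocking down the top hit.  Implements the
    cell-count-weighted least-squares screen that regresses per-strain
    lifespan change on per-gene expression log2 fold change, lifespan
    assay statistics (group summaries, percent extension, Kaplan-Meier
    curves, log-rank tests, LOESS dose-response), differential-expression
    calling with Benjamini-Hochberg adjustment, and stratification of
    differentially expressed genes by promoter chromatin state and
    expression abundance, with Fisher-exact gene-set enrichment.  A
    synthetic-data module generates inputs with planted ground truth so
    that every stage of the pipeline is testable without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    survival,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
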