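Package: editlens
Title: RNA Editing Discovery, Differential Analysis and Expression Integration
Version: 0.1.0
Authors@R:
    person("editlens", "maintainers", email = "maintainers@editlens.dev",
           role = c("aut", "cre"))
Description: A pipeline for quantitative analysis of RNA editing from
    RNA-seq variant candidates: two-stage hard/editing filter cascade on
    VCF-annotated variants, per-sample editing-frequency estimation,
    editing-type, region and coding-consequence annotation, gene-level
    aggregation of editing-supporting reads, negative-binomial Wald
    differential testing for both editing and expression, TPM and
    unsupervised summaries (PCA, sample correlation, shared-event counts),
    nine-quadrant editing-by-expression integration with enzyme-expression
    correlation, and hypergeometric pathway over-representation analysis.
    Includes a fully specified synthetic-data generator with ground-truth
    tables so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    stats,
    utils,
    tools,
    methods,
    jsonlite,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    SummarizedExperiment,
    rtracklayer,
    VariantAnnotation
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
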