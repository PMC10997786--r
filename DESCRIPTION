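Package: metareplicate
Title: Metacell Pseudoreplicates for Time-Series Single-Cell Differential Expression
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Constructs metacells from time-series single-cell RNA-seq data and
    uses them as statistical replicates ("metareplicates") for per-gene
    quadratic regression ANOVA over time. Three replicate-generation
    strategies are provided: a heterogeneity-preserving k-nearest-neighbour
    kernel archetype method (sMetacells), random same-type cell averaging
    (rMetacells), and per-sample pseudobulk aggregation. Significant genes
    (BH FDR and R-squared gated) are classified into one of eight expression
    velocity trends from the fitted quadratic and observed per-day means.
    Includes a seeded negative-binomial count simulator with planted temporal
    gene programs, variance diagnostics comparing metacell strategies, and a
    command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    jsonlite,
    methods,
    optparse,
    stats,
    utils
Suggests:
    cluster,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
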