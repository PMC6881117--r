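Package: pepnet
Title: Dense Intracortical Neuropeptide Network Discovery from Single-Cell RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for discovering dense peptidergic modulatory networks from
    single-cell RNA-seq of cortical neurons. Implements peak-expression
    (pFPKM-style) statistics and ranking, detection-fraction and co-expression
    summaries, cross-area conservation analysis, trimmed-mean neuron-type
    expression profiles, selection of neuropeptide precursor (NPP) and
    neuropeptide-selective GPCR (NP-GPCR) gene sets with cognate-pair
    construction, a gene-subset cell-type classification benchmark built on
    linked autoencoders with hierarchical quadratic discriminant analysis and a
    taxonomy resolution index, and type-by-type peptidergic coupling-matrix
    prediction with G-alpha-family aggregation. Ships a negative-binomial
    synthetic-data generator emulating a two-area, hierarchically typed
    cortical census so the full pipeline is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    tidyr,
    utils,
    withr
Suggests:
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
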