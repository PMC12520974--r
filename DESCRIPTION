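Package: proxiscore
Title: Spatial Proximity Scores and kNN Label Transfer for Single-Cell
    Spatial Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies spatial enrichment of one cell type around subtypes of
    another in single-cell resolved spatial transcriptomics data. Implements
    k-nearest-neighbour label transfer from an annotated single-cell reference
    to spatial cells in a shared 2-D embedding, an observed-versus-expected
    nearest-neighbour proximity score with a one-tailed exact binomial test,
    per-condition cluster composition summaries, and a gene-set change-fraction
    statistic. Ships a synthetic-data generator that emulates a multi-sample,
    two-condition muscle-tissue study design with a tunable planted attraction
    of a query cell type (e.g. tissue-resident macrophages) toward one target
    endothelial subtype, so the whole pipeline is testable with known ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
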