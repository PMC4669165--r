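Package: signalmods
Title: Signed Signaling Networks and Differentially Regulated Modules
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds signed, directed gene-level signaling networks from
    curated pathway collections, integrates them with differential-expression
    results through gene-set over-representation (Fisher's exact test) and
    ranking-based enrichment (Wilcoxon rank-sum), extracts differentially
    regulated modules with a Steiner-tree heuristic over DEG-induced terminal
    nodes, and quantifies cross-dataset module concordance by graph overlap,
    fold-change correlation, and Steiner-node status agreement. Includes a
    synthetic-data generator for pathway collections and two-group expression
    data with planted structure, so every pipeline stage is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
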