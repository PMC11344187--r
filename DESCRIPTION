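Package: stancenet
Title: Temporal Multilayer Network Analysis of Vaccine-Stance Echo Chambers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds directed, weighted multilayer networks from stance-labeled
    bulletin-board threads (provaccination, vaccine hesitant, antivaccination
    layers) and quantifies echo chambering over time. Provides a parser and
    emitter for a PTT-style thread-text dialect, user anonymization, keyword
    filtering and two-rater label ingestion; flattening of comments into
    directed commenter-to-author edge records with sentiment weights and
    opposing-camp reassignment of "boo" reactions; cumulative temporal
    snapshots; node-, layer- and network-level chambering metrics (in/out
    degrees, cross-layer degree diversity, pairwise Spearman rank
    correlations, node overlap, Shannon participation entropy, hardliner and
    diverse-node selection, discrete power-law fits with bootstrap
    goodness-of-fit); board-level bootstrap confidence intervals; and a
    synthetic forum generator with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    dplyr,
    igraph,
    purrr,
    readr,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
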