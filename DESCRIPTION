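Package: phasenet
Title: Phase-Synchronisation Connectivity and Network-Based Statistics for
    Resting-State MEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for resting-state source-space MEG connectivity
    analysis: band-limited Hilbert phase extraction, weighted phase lag index
    (wPLI) connectivity, and the network-based statistic (NBS) with covariate
    GLMs and permutation-based family-wise error control, for group contrasts
    and continuous-predictor associations. Includes a synthetic-cohort
    generator that plants known phase-lag coupling, group effects, outcome
    associations, and postnatal nutrient-intake records so that every stage of
    the pipeline can be validated against ground truth, plus demographics
    comparison, hub identification, intake summaries and BrainNet Viewer
    export.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
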