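Package: pfcnet
Title: Neurotransmitter Network Analysis of K+-Evoked Prefrontal Cortex
    Microdialysis with Behavioral Economics and Vigilance Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for studying how simulated galactic-cosmic-radiation
    exposure reorganizes prefrontal-cortex neurotransmitter networks and behavior
    in mice. Provides an exponential behavioral-economic demand model with
    essential-value estimation, a titrating psychomotor vigilance task engine,
    K+-evoked microdialysis summaries (basal, cumulative and percent-basal
    levels with group statistics), thresholded Pearson correlation networks,
    iterative random forest leave-one-out-prediction (iRF-LOOP) directed
    network inference with signed edges, and pairwise Granger causality on
    short per-subject time series. A seeded synthetic-cohort generator with
    group-specific response kinetics and cross-neurotransmitter coupling makes
    every stage testable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    readr,
    rlang,
    jsonlite,
    yaml,
    ranger,
    igraph,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    lmtest,
    optparse
Config/testthat/edition: 3
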