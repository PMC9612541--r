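Package: bodymapr
Title: Analysis and Visualization of Pain Body-Map Endorsement Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for working with patient-reported pain body-map data
    captured on the 74-segment CHOIR Body Map (CBM) code system. Parses
    delimited segment-endorsement strings into per-patient and aggregated
    per-segment tables, compares endorsement between groups with per-segment
    two-proportion z-tests, relates endorsement to continuous covariates
    (e.g. NRS pain intensity or PROMIS t-scores) with per-segment logistic
    regression, applies family-wise multiplicity correction, computes pairwise
    co-occurrence matrices, and renders body-map choropleths, endorsed-area
    histograms, difference maps and co-occurrence heatmaps. Includes a seeded
    synthetic-cohort generator so every statistic and plot is testable without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    S4Vectors,
    SummarizedExperiment,
    ggplot2,
    rlang
Suggests:
    testthat (>= 3.0.0),
    xml2,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
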