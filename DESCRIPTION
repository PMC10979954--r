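Package: cytonet
Title: Functional Connectivity and Regional Cytokine Signature Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end analysis pipeline linking resting-state
    functional connectivity to regional cytokine signatures in a mouse
    model of Alzheimer's disease. Provides motion scrubbing and nuisance
    regression of ROI time series, band-pass filtering, Fisher-z
    aggregation of connectivity to anatomical systems, mixed-effects
    group contrasts with FDR control, weighted brain-graph metrics with
    hub scoring, multiplex cytokine panel cleaning, and from-scratch
    orthogonalized partial least squares modelling with VIP selection,
    repeated cross-validation and permutation significance testing. A
    synthetic-data module emulates the study design so the full pipeline
    is testable without access to raw scans.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    lme4,
    signal,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
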