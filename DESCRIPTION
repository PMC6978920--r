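Package: ratconnectome
Title: Multiscale Resting-State Connectome, Response-Bias, and Arc Ensemble
    Analysis for Longitudinal Rodent Training Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Builds thresholded weighted functional-connectivity graphs from
    region-of-interest (ROI) resting-state time series and computes graph
    metrics (node strength, degree, weighted clustering, characteristic path
    length, small-worldness, and the rich-club curve with degree-preserving
    null models), seed-based connectivity with hemisphere averaging, a
    behavioral response-bias index from maze trial logs, and rule-based
    nuclear/cytoplasmic classification of Arc catFISH cell populations with
    ensemble similarity scores. Includes the signal-conditioning chain
    (detrending, nuisance regression, band-pass filtering), mixed
    repeated-measures group statistics with per-degree rich-club comparison,
    and a synthetic-data layer that plants known covariance structure,
    behavioral bias, and cell-class ground truth so every stage is testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    graphics,
    S4Vectors,
    igraph,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    RNifti
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
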