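Package: avihrf
Title: Event-Related fMRI Analysis for Awake Pigeons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for event-related fMRI in awake pigeons:
    a parametric double-gamma hemodynamic response function (HRF) with
    species-specific canonical parameter sets, bounded nonlinear
    least-squares HRF estimation from trial-averaged BOLD responses,
    first-level general linear models for a Go/NoGo colour discrimination
    task with permutation-based cluster-extent inference, time-series
    preprocessing and quality-control statistics (temporal SNR, median
    absolute deviation of motion parameters), and signal-detection-theory
    scoring of mandibulation responses recorded with a differential
    piezo-electric sensor.  A bundled synthetic-session generator emulates
    the scanning protocol (event designs, 4D BOLD, motion traces, piezo
    logs) so the whole pipeline is testable without scanner data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    minpack.lm,
    withr,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
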