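Package: bmorim
Title: Minimum Rim Area Morphometry of the Optic Nerve Head from Radial
    OCT Star Scans
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computes the Bruch's membrane opening (BMO) based minimum rim
    area of the optic nerve head from segmented radial SD-OCT star scans.
    Two optimization strategies are implemented: independent per-sector
    trapezoid minimization (the sequential BMO-MRA) and exact simultaneous
    minimization of a triangulated rim surface under a shared-vertex
    continuity constraint (the global BMO-gMRA), solved by cyclic dynamic
    programming with optional continuous refinement. Includes a synthetic
    optic-nerve-head phantom and cohort generator with known ground truth,
    Garway-Heath sector aggregation, and paired diagnostic-evaluation
    statistics (ROC AUC, DeLong test, partial AUC with stratified bootstrap
    comparison, sensitivity at fixed specificity, Benjamini-Hochberg
    correction), plus a JSON/CSV toolchain and command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
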