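Package: hgr
Title: Head Gesture Recognition from Quaternion Orientation Streams
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classification of head gestures recorded as unit-quaternion
    orientation streams from a head-mounted inertial measurement unit.
    Provides quaternion algebra utilities, segmentation of gestures from
    continuous motion by thresholding median-filtered angular velocity,
    dynamic time warping (DTW) template classification with templates
    learned by quaternion-aware DTW barycenter averaging (Markley
    eigen-averaging), a per-subject bagged DTW voting ensemble,
    PCA-feature nearest-neighbour baselines (single and two-stage),
    leave-one-subject-out evaluation, and a synthetic head-gesture
    generator for benchmarking without access to recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
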