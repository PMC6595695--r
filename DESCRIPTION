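Package: gaitphase
Title: Gait-Phase Clustering and Clinical Validation for Foot-Worn IMU Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing standardized 4x10 m walk tests recorded with
    foot-worn six-axis inertial measurement units. Segments single strides from
    the medio-lateral gyroscope channel by subsequence dynamic time warping with
    minima-based boundary refinement, isolates turning strides with a 20-degree
    turning-angle rule extended by a gamma-tail adjacency criterion, clusters
    straight strides into constant and non-constant gait by crop-, median-,
    distribution-, k-means- and percentile-based methods with an ordering
    post-processor, computes spatio-temporal gait parameters (including
    zero-velocity-update double-integrated stride length), aggregates cluster-wise
    per-subject features, and validates the clinical information in each gait
    cluster with a Fisher-score / support-vector-machine / ROC-AUC pipeline.
    Includes a synthetic walk-test generator so the full pipeline can be
    exercised without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    fitdistrplus,
    e1071,
    pracma,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC
Config/testthat/edition: 3
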