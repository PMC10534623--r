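Package: immgru
Title: Interacting Multiple Model Tracking with Recurrent Motion Models
    for Low-Rate Telemetry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tracks manoeuvring animal targets (small birds observed by a
    scanning Lidar or any low-refresh-rate sensor) in the plane. A bank of
    small gated-recurrent-unit (GRU) motion models, each trained on a band
    of sampling intervals, produces per-model trajectory predictions that
    are fused by an interacting-multiple-model (IMM) mechanism. An
    approximate one-step state-transfer matrix (a fitted convex blend of
    constant-velocity and constant-turn transitions) turns each neural
    prediction into a linear transition so that covariances can be
    propagated and model probabilities updated by Bayes' rule. Candidate
    scan points are gated by a mixture-Gaussian predictive density, and a
    one-step-deep back-tracking beam revises the previous measurement
    association when a later scan contradicts it. Includes a trajectory and
    scan simulator, classical baselines (UKF, IMM-UKF, bootstrap particle
    filter, single-model GRU-EKF) and a Monte-Carlo evaluation harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
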