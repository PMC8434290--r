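Package: gaitsynth
Title: Synthetic IMU Data Generation and BiLSTM Joint-Angle Estimation for Gait
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for generating synthetic training data for wearable-sensor
    gait analysis. Joint-angle trajectories for a lower-limb rigid-body chain
    (pelvis-thigh-shank-foot) are augmented with magnitude-offset, magnitude-warp
    and time-warp operators, virtual inertial measurement unit (IMU) signals are
    simulated from the augmented kinematics by forward kinematics and analytic
    differentiation, and bidirectional LSTM sequence-to-sequence networks are
    trained to predict 3-DoF hip and knee rotations from multi-sensor IMU
    streams. Includes a synthetic multi-subject gait cohort generator with
    ground-truth events, gait-cycle preprocessing (resampling, zero-phase
    Butterworth filtering, segmentation, zero-padding), per-cycle accuracy
    metrics, and MANOVA with Tukey HSD comparisons across training-set variants.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    signal,
    pracma,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
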