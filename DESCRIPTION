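Package: wristcast
Title: Predicting Wrist Rotation Angles from Proximal Arm Kinematics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for predicting wrist rotation angles (flexion/extension,
    abduction/adduction and forearm pronation/supination) from elbow and
    shoulder kinematics during pick-and-place object transports, for the
    automation of motorized wrists in upper-limb prostheses. Includes a
    synthetic motion-capture generator with known ground truth, rigid-body
    joint-angle extraction by ordered Euler decomposition, trajectory
    preprocessing (dynamic time warping synchronization, zero-phase Butterworth
    filtering, time normalization, per-subject centering), pick/place event
    detection, shallow feed-forward and time-delay neural networks trained
    with Bayesian-regularized Levenberg-Marquardt optimization, a linear
    regression baseline, and an evaluation harness.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    graphics,
    jsonlite,
    signal,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
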