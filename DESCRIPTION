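Package: gaitsig
Title: Markerless Gait Kinematics, Quality Control and Phenotyping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for turning 3D lower-body keypoint trajectories (Root, left/right
    anterior superior iliac spine, lateral femoral epicondyle and lateral malleolus)
    into camera-frame hip and knee flexion-angle time series, time-normalized gait
    cycles, and interpretable gait phenotypes. Includes Procrustes-aligned mean
    per-joint position error for benchmarking keypoint predictions against motion
    capture, k-means++ gait-cycle quality control with detection and correction of
    direction-reversed trials, dynamic-time-warping permutation tests and Pearson
    correlation against reference signatures, nearest-centroid and multilayer
    perceptron classification of spinal cord injury versus healthy gait, Shapley-value
    attribution of discriminative gait-cycle time windows, and a seeded synthetic gait
    generator for fully reproducible end-to-end validation.
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
    vegan,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
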