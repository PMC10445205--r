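Package: dosewarp
Title: Contour-Guided Deformable Registration and Dose Accumulation for
    CBCT-Guided Pelvic Radiotherapy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Deformable image registration between planning CT and daily
    CBCT-like volumes of the male pelvis, and the downstream dose-monitoring
    chain built on it. Provides three weakly supervised convolutional
    registration networks driven by anatomical scans, organ label images, or
    both; a classical multi-resolution B-spline free-form deformation
    baseline optimised under normalised mutual information; geometric
    evaluation (Dice, average surface distance, Hausdorff and 95th-percentile
    Hausdorff distances); Jacobian-determinant folding analysis; and
    deformation-based warping and summation of fraction doses with
    dose-volume-histogram index reporting. A synthetic pelvic phantom
    generator with analytically known diffeomorphic deformations makes the
    whole chain testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
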