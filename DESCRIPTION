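Package: sitsense
Title: Smartphone IMU Sitting-Posture Recognition Pipeline
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A tested, reusable pipeline for recognizing static sitting
    behaviors (left, right, front, back and straight leans) from tri-axial
    smartphone accelerometer, gyroscope and magnetometer streams sampled at
    50 Hz. Provides a synthetic seated-posture signal generator emulating a
    trunk-mounted sensor, zero-phase denoising and max-abs normalization,
    sliding-window segmentation, an 84-feature morphological and entropy
    feature bank, correlation-based feature-subset selection (CFS merit with
    symmetrical uncertainty) searched by binary particle swarm optimization
    with an exhaustive-search oracle, Gaussian naive Bayes,
    K-nearest-neighbor (Euclidean or median-binarized Hamming) and
    one-against-all RBF-kernel support vector machine classifiers, and
    stratified holdout or k-fold cross-validation evaluation with confusion
    matrices and per-activity recall. Results are tibbles throughout, with
    broom-style tidy() and glance() methods and ggplot2 autoplot() methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    class,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
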