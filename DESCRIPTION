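Package: gripdecode
Title: Decoding Sequential Finger-Grip Movements from Data-Glove Kinematics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for discriminating highly similar sequences of pinch-grip
    hand movements recorded with an exoskeleton data glove. Implements the
    full decoding chain: calibration-based normalization, angular-velocity
    preprocessing, multivariate dynamic time warping with data-driven
    template selection and warp-resampling to a fixed-length feature space,
    one-vs-rest linear support vector machine classification with the
    SVM-light default box constraint, a stacked bidirectional LSTM sequence
    classifier for variable-length trials, leave-one-run-out,
    leave-one-subject-out and two-fold cross-validation, permutation-based
    chance-level estimation, and a seeded synthetic data-glove simulator for
    benchmarking without hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    e1071,
    jsonlite,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    readr,
    generics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    kernlab,
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
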