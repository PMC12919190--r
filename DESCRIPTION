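Package: kinscore
Title: Distribution-Aware Severity Scoring of Motor-Exam Videos from Pose Keypoints
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying motor severity in standardized clinical
    motor exams (MDS-UPDRS Part III style tasks) from 2D pose-keypoint time
    series. Reads and cleans pose-estimator output, segments task execution
    windows, constructs task-specific kinematic signals and features
    (amplitude, frequency, decrement, rhythm), and fits a dual-branch
    ordinal model (temporal convolutional branch over the signal plus a
    feature multilayer perceptron) with a rank-consistent cumulative-logit
    head, trained under a disagreement-aware loss that targets the mean of a
    multi-rater panel while penalizing predictive variance. Includes
    consensus-aware evaluation metrics (within-one-class and
    distribution-aware accuracies, agreement decomposition,
    complexity-consensus regression, composite scores, medication
    contrasts) and a severity-parameterized motion-and-rater simulator for
    end-to-end testing without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    readr,
    signal,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
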