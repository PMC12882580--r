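Package: tracekin
Title: Kinematic Analysis of Stylus Shape-Tracing Tasks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for digital phenotyping of movement from stylus
    shape-tracing and reaction-time tasks. Generates pure-frequency target
    shapes defined by their angular frequency, simulates synthetic
    three-group cohorts (autistic, parkinsonian, control) tracing those
    shapes, preprocesses raw stylus logs (validation, angular trimming,
    spline resampling), extracts nine per-trial kinematic features
    (speed, acceleration, jerk, minimum and maximum speed, sub-movement
    percentage, speed-curvature power-law exponent, spectral arc length
    smoothness, tracing error), fits effects-coded linear mixed models
    with follow-up group contrasts and BIC-approximated Bayes factors,
    and runs a two-stage KNN/random-forest/SVM classification grid over
    kinematic and questionnaire feature sets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    class,
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    lmerTest,
    purrr,
    randomForest,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tools,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
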