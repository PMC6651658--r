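Package: quathar
Title: Orientation-Invariant Human Activity Recognition from a Pocket-Worn
    Inertial Sensor
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Recognises six human activities (sedentary, standing, walking,
    walking upstairs, walking downstairs, postural transitions) from a
    loosely-worn pocket inertial measurement unit and barometric altimeter,
    without assuming any fixed device orientation. The sensor's upright
    orientation is learned on-line during detected walking and
    quaternion-derived features (pitch/roll angular-velocity power,
    shortest-rotation tilt, barometer-fused vertical velocity) feed a
    hierarchical tree of CART stumps. Includes a synthetic session simulator,
    virtual re-orientation utilities, evaluation metrics (Cohen's kappa,
    per-class sensitivity and specificity with bootstrap confidence
    intervals, Shannon entropy of feature/class distributions) and plotting
    helpers.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    e1071,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
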