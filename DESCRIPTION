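Package: grfproxy
Title: Proxy Measurement of Vertical Ground Reaction Forces from a
    Single Accelerometer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Reconstructs left- and right-foot vertical ground reaction
    forces (vGRF) from a single 3-axis accelerometer worn on the trunk.
    Acceleration is decomposed into left- and right-foot components with
    gait-event-based membership functions, and each foot's vGRF is
    modelled as a degree-2 polynomial nonlinear moving-average (Volterra)
    model over lagged decomposed channels, with model structure selected
    by (iterative) orthogonal forward regression ranked by error
    reduction ratio. Includes gait-event detection from force-threshold
    crossings, gait-cycle segmentation, per-phase and critical-point
    (VP1/VP2/TR) error analysis with RMSE and relative RMSE, a seeded
    synthetic gait-data generator with a biomechanically shaped mode and
    an exact oracle mode, and tidy/broom-style accessors for fitted
    models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
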