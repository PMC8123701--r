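Package: driverisk
Title: Driving Risk Levels from Personality Traits and Telematics Event Counts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for evaluating the relative driving risk of professional
    (truck) drivers from Big Five personality traits and rule-detected aberrant
    driving events. Implements rule-based detection of six aberrant behaviors
    from per-second telemetry, Jenks natural-breaks classification with
    goodness-of-variance-fit and elbow selection of the class count, an
    additive driving-risk index with five risk levels, single-hidden-layer
    neural-network prediction of behavior classes and risk from traits, and
    mean-substitution sensitivity analysis with leave-one-factor-out ablation.
    Includes a synthetic-cohort generator with calibrated trait-behavior
    correlation structure so the full pipeline is testable without fleet data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
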