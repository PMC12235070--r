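Package: mudeltaf
Title: Motor Unit Discharge Analysis and Paired-Motor-Unit Delta-F Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for motor-unit spike trains decomposed from
    high-density surface electromyography recorded during isometric
    ramp-and-hold and triangular force contractions. Provides quality control
    of decomposed discharge trains (pulse-to-noise ratio gating, interspike
    interval bounds, discharge-rate variability exclusion), per-unit discharge
    metrics (instantaneous and mean discharge rate, coefficient of variation
    of the interspike interval, recruitment threshold from normalized torque),
    estimation of persistent inward currents by the paired-motor-unit delta-F
    method with support-vector-regression smoothed rate profiles, laterality
    indices, and the group statistical layer (pooled t tests, chi-square
    tests, linear mixed-effects models with estimated marginal means, Pearson
    correlations, robust LOESS). A phenomenological motoneuron-pool simulator
    with analytically known recruitment/derecruitment hysteresis supplies
    ground truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    e1071,
    emmeans,
    jsonlite,
    lme4,
    lmerTest,
    signal,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
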