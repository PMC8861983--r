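Package: stemrsa
Title: Multivariate Analysis of 3D Femoral Stem Migration from
    Radiostereometric Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing three-dimensional femoral stem migration
    measured by radiostereometric analysis (RSA). Provides rigid-body
    migration metrics (six degrees of freedom, total translation and
    rotation, maximum total point motion), marker-based quality control
    (mean error of rigid-body fitting, condition number) and interquartile
    outlier rules, a hierarchical linear mixed model that treats both the
    follow-up time point and the migration axis as repeated measures with
    unstructured (Kronecker or full) within-subject covariance estimated by
    REML and Kenward-Roger adjusted F-tests, a Monte Carlo power study
    comparing the multivariate model against univariate and surrogate-metric
    t-tests under rotation of the measurement frame, a two-proportion
    sample-size calculator, and a synthetic trial generator that emulates a
    two-arm randomised RSA trial for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    MASS,
    car,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    nlme,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
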