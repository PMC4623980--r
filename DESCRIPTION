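Package: bftbiom
Title: Biometric Relationships and Seasonal Condition of Atlantic Bluefin Tuna
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to standardize mixed-type length and weight measurements of
    Atlantic bluefin tuna (Thunnus thynnus) to common units, fit allometric
    weight-length relationships by coefficient-of-variation-weighted
    Gauss-Newton nonlinear regression, run quantile-regression and bootstrap
    sensitivity analyses, simulate expected size-sampling distributions of an
    age-structured population under knife-edge selectivity, and model monthly
    somatic condition as a seasonal adjustment to the allometric exponent.
    Includes a synthetic fishery-data generator emulating the unbalanced,
    size-truncated, mixed-measurement structure of real bluefin sampling
    programmes, plus the published coefficient tables as fixtures.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    MASS,
    minpack.lm,
    emmeans,
    car
Config/testthat/edition: 3
RoxygenNote: 7.3.3
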