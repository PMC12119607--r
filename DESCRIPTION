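Package: qaopbn
Title: Quantitative Adverse Outcome Pathway Modeling with Gaussian
    Bayesian Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Probabilistic risk estimation over an adverse outcome pathway
    (AOP) for cigarette-smoke-induced airway mucus hypersecretion. Provides
    lognormal Bayesian resampling of sparse in vitro fold-change data,
    static linear-Gaussian Bayesian network fitting per exposure repetition
    with threshold-exceedance probabilities by forward sampling, dynamic
    Bayesian network transition models (ridge regression with closed-form
    leave-one-out cross-validation and likelihood-weighted inference),
    odds-ratio construction against the air-exposure control, a simple
    reverse-dosimetry unit bridge between culture-insert doses and airway
    surface deposition, and a synthetic-data generator emulating repeated
    whole-cigarette-smoke exposure of donor-derived bronchial epithelial
    cultures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS,
    optparse
Config/testthat/edition: 3
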