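Package: livhte
Title: Local Instrumental Variable Estimation of Heterogeneous Treatment
    Effects in Target Trial Emulations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates marginal and personalised treatment effects from
    observational cohorts with a continuous preference-based instrument,
    using the local instrumental variable (LIV) approach: a probit
    treatment-propensity first stage, a flexible outcome model in the
    estimated propensity, analytic marginal treatment effects (MTE), and
    personalised effects (PeT) obtained by integrating the MTE over the
    latent resistance values compatible with each patient's observed
    treatment. Includes a synthetic electronic-health-record cohort
    generator with a cluster-level tendency-to-prescribe instrument and
    essential heterogeneity, target-trial cohort construction (eligibility,
    subgroups, complete-case filtering, RCT-eligibility split), instrument
    diagnostics, selection-on-observables and linear-IV comparators
    (IPTW-RA with recycled predictions, two-stage least squares, Wald),
    stratified bootstrap confidence intervals, and an end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    glmnet,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
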