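Package: papower
Title: Design of School-Based Cluster Trials for Children's Physical Activity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for planning cluster-randomised evaluations of children's
    physical-activity interventions in schools. Simulates multilevel
    longitudinal accelerometer-style outcome data (pupils within schools
    within studies, repeated waves), estimates school-level intra-cluster
    correlation coefficients (ICCs) from three-level mixed models with
    delta-method confidence intervals on the logit scale, estimates cluster
    and individual autocorrelations (CAC, IAC) with Fisher-z meta-analytic
    pooling, and computes required numbers of schools or achieved power for
    two-arm cluster RCTs (with and without baseline adjustment) and
    cross-sectional or cohort stepped wedge designs using the Hussey-Hughes
    treatment-effect variance.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    metafor,
    pracma,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    Matrix,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
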