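Package: pjiscore
Title: Diagnostic Agreement, Decision Curves, and Misdiagnosis Costs for
    Suspected Periprosthetic Joint Infection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparing a synovial-fluid biomarker probability
    score against physician standard-of-care in suspected periprosthetic
    joint infection (PJI). Provides a synthetic clinical-vignette cohort
    generator with configurable biomarker distributions, missingness and
    two-stage rater simulation; constant-value imputation of incomplete
    biomarker panels; a two-stage Gaussian-mixture / logistic surrogate
    probability score on a 0-100 scale with triage and forced-call
    thresholds; agreement statistics against a clinical reference (overall,
    positive and negative percent agreement with Wilson intervals, Gwet's
    AC1 with bootstrap intervals, pooled multi-rater estimates, indecision
    rates); decision curve analysis with net-benefit improvement and an
    economically derived threshold probability; and a decision-analytic
    model of misdiagnosis costs with a Monte-Carlo patient-level check.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    mclust,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
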