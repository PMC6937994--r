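Package: bayesdx
Title: Sequential Bayesian Diagnostic Updating and Decision Support for
    Pneumonia Severity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Likelihood-ratio arithmetic and sequential Bayesian (Fagan
    nomogram) updating for severity-of-illness prediction in
    community-acquired pneumonia.  Chains CURB-65 pretest strata with
    serial biomarkers (procalcitonin, lactate) under conditional
    independence, computes Bayesian Diagnostic Gains (absolute and
    relative), the Bayesian Number Needed to Diagnose, branch
    enumeration with marginal branch probabilities, a disposition
    decision tree with configurable rules, a Monte-Carlo cohort
    simulator used as an empirical oracle, and a one-way ANOVA stage
    comparison.  Ships an embedded pneumonia case study that reproduces
    the published tables offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
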