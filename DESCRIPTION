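Package: crpflare
Title: On-Treatment Risk Stratification from CRP Kinetics and Early
    Adverse Events in Advanced Renal Cell Carcinoma
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies longitudinal on-treatment C-reactive protein (CRP)
    trajectories of advanced renal cell carcinoma patients under first-line
    immunotherapy combinations into flare-response, response and non-response
    kinetics; derives the early-onset flag for treatment-related adverse
    events; combines both factors into a three-tier on-treatment risk model;
    and provides the accompanying inference machinery: Fisher and
    Freeman-Halton exact tests by full fixed-margin enumeration (with a
    Monte-Carlo fallback), likelihood-ratio chi-square tests, odds ratios,
    binomial logistic regression summaries with Nagelkerke R-squared and
    stepwise block selection, Kaplan-Meier estimation with median confidence
    intervals, the Gehan-Breslow generalized Wilcoxon test, and univariable
    Cox regression. A synthetic-cohort generator emulates the statistical
    structure of such studies so the full pipeline is testable without
    patient-level data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
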