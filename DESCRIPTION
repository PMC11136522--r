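Package: ehrnbc
Title: Naive Bayes Cumulative Risk Scoring for Suicide-Attempt Prediction
    from Longitudinal EHR Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Implements an electronic-health-record based risk prediction
    workflow for incident suicide attempts: ICD-9 wildcard case definitions
    and cohort inclusion rules, first-occurrence binary concept features,
    site-specific naive Bayes partial risk scores (log prevalence ratios),
    longitudinal cumulative risk trajectories with specificity-quantile alert
    thresholds, and per-site evaluation (sensitivity, PPV, NPV, AUC with
    Hanley-McNeil standard errors, prediction lead time, decile enrichment)
    aggregated across sites under a federated contract in which only summary
    statistics leave a site.  A multi-site synthetic EHR generator with
    planted per-concept odds ratios stands in for protected clinical data so
    the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    data.table (>= 1.14.0),
    jsonlite,
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
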