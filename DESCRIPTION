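Package: postriage
Title: Postoperative Triage Misclassification, Risk-Matched Cohorts, and
    Value of Care
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for auditing equity in postoperative intensive-care triage
    from admission-level risk scores. Classifies admissions as overtriaged
    (low-acuity patients sent to an ICU) or undertriaged (high-acuity patients
    sent to a general ward) using percentile thresholds on model-predicted
    risks of hospital mortality and prolonged ICU stay; builds risk-matched
    control cohorts by K-nearest-neighbor matching; computes the risk-adjusted
    value-of-care statistic (inverted observed-to-expected mortality per unit
    cost, normalized to a pooled median of 1); discovers sociodemographic
    phenotypes by K-means clustering with elbow selection over the
    within-cluster sum of squares; and produces multiplicity-adjusted
    two-group comparison tables. Includes a seeded synthetic cohort generator
    with planted phenotype structure so the whole pipeline is testable without
    access to protected health data, plus power calculations for two-group
    designs with unequal allocation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    stats,
    tibble,
    tools,
    utils,
    withr,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
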