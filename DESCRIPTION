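Package: tshfrax
Title: TSH-Weighted Fracture Risk Assessment for Thyroid Cancer Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fracture-risk assessment pipeline for differentiated thyroid
    carcinoma (DTC) patients on postoperative TSH suppression therapy.
    Implements a TSH-to-added-years weighting table that converts the degree
    of TSH suppression into an effective age for FRAX-style 10-year fracture
    probability estimation, a pluggable surrogate risk calculator, WHO
    bone-status classification from DXA T-scores, ROC/Youden diagnostic
    evaluation (AUC, optimal cutoff, sensitivity, specificity, PPV, NPV),
    the group-comparison statistics used in case-control bone-health studies,
    and a seeded synthetic cohort generator for end-to-end testing without
    patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
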