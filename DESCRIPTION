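Package: incrisk
Title: Incremental Value of Circulating Biomarkers in Clinical Risk Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify the incremental predictive value of circulating
    biomarkers added to an established baseline cardiovascular risk score for a
    dichotomized coronary artery calcification (CAC) outcome. Implements nested
    logistic regression with iteratively reweighted least squares, univariate
    marker screening and stepwise selection, Mann-Whitney AUC with DeLong
    variance and the paired DeLong test, two-category net reclassification
    improvement (NRI) at a fixed risk threshold, integrated discrimination
    improvement (IDI), and Hosmer-Lemeshow decile calibration. Includes a
    synthetic rheumatoid-arthritis cohort generator with a two-part
    (zero-inflated lognormal) Agatston score model so the complete
    training/validation workflow can be exercised without patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
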