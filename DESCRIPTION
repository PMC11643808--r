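Package: heilipids
Title: Diet Quality Scoring, Serum Lipidomic Signatures and Cardiometabolic Risk
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores diet quality with a 10-component, 0-11 point healthy
    eating index built for the MIDUS cohort questionnaire, derives a serum
    lipidomic signature of that index by LASSO regression with honest
    leave-one-out cross-validated training scores, classifies metabolic
    syndrome by the updated ATP III definition, estimates 10-year
    atherosclerotic cardiovascular disease risk with the 2013 ACC/AHA pooled
    cohort equations, and fits tiered covariate-adjustment models linking
    the signature to cardiometabolic biomarkers. Includes a calibrated
    two-wave synthetic cohort generator with planted effects so the whole
    pipeline is testable end to end without access to restricted cohort
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    glmnet,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
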