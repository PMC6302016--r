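Package: uroscreen
Title: Diagnostic Accuracy of Automated Urine-Culture Screening Analysers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to evaluate automated urine screening analysers (flow
    cytometry or flow imaging bacteria and leukocyte counts) against urine
    culture as the gold standard. Provides culture ground-truth labelling
    with configurable CFU/mL thresholds, empirical ROC curves and AUC,
    single-marker and combined bacteria-OR-leukocyte cut-off optimization
    (Youden index or sensitivity-floor criteria), sensitivity, specificity,
    predictive values and culture-workload reduction with Wilson intervals,
    two-device comparison at matched sensitivity with bootstrap intervals,
    and a seeded synthetic cohort generator with closed-form binormal AUC
    calibration for fully reproducible pipeline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    readr,
    stats,
    tibble,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
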