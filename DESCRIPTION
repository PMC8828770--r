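Package: appliscore
Title: Biomarker Applicability Prediction with Paired Outcome and
    Confidence Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for applying gene-expression biomarkers to individual
    cancer patients with an explicit measure of per-patient applicability.
    A clinical outcome prediction model (CPM) maps a signature score plus
    clinical covariates to a prognostic P-score (probability of pathologic
    complete response, or a Cox/survival-forest risk), and a predictability
    prediction model (PPM) is trained on the CPM's own correct/incorrect
    (or well/poorly predicted) labels to emit a confidence C-score for each
    patient. Includes the effective-pair rules and sample-specific
    concordance decomposition used to label survival predictions under
    censoring, class-balanced random-forest training, repeated stratified
    cross-validated AUC, drop-predictor importance, confidence-sorted
    accuracy curves, generic weighted signature scoring, Spearman
    nearest-centroid molecular subtyping, and seeded synthetic cohort
    generators for testing the whole framework at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    randomForest,
    ranger,
    survival,
    pROC,
    jsonlite,
    withr,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
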