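Package: metapred
Title: Meta-Prediction of 10-Year Incident Coronary Artery Disease Risk
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A stacked ("meta-prediction") framework for 10-year incident
    coronary artery disease risk. Stage-1 gradient-boosted models trained on a
    prevalent-disease cohort predict baseline and future diagnoses and
    risk-factor values under controlled feature scopes; their predictions are
    stacked with measured features and polygenic risk scores into a final
    incident-risk classifier. Downstream machinery clusters cases into risk
    subgroups by their attribution profiles and simulates counterfactual
    clinical interventions (LDL, HbA1c, systolic blood pressure lowering).
    Includes a synthetic biobank generator with known ground-truth risk
    mechanisms, cohort construction with eligibility filtering and balanced
    control allocation, feature engineering (ordered target encoding, chained
    imputation, medication keyword flags, PRS computation), and evaluation
    metrics (AUROC/AUPRC with bootstrap intervals, Youden cutoffs,
    reclassification tables, NRI, IDI, Harrell's concordance index).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    xgboost,
    ranger,
    survival,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    mclust,
    withr,
    data.table
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
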