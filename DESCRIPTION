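Package: wardaki
Title: Refined KDIGO Phenotyping and Early Prediction of Acute Kidney Injury in General Wards
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Electronic phenotyping of acute kidney injury (AKI) and acute kidney
    disease (AKD) from irregularly sampled ward serum-creatinine series. Implements
    the standard KDIGO creatinine criteria and a refined operational definition that
    estimates the baseline as the lowest value in the prior 7-day window after an
    exclusion rule for transient dips, and that requires a minimum absolute increase
    of 0.3 mg/dL, reducing misclassification of low-baseline fluctuations. Includes
    AKD (nonrecovery within 7 days) adjudication, day-level label construction for
    early-warning prediction, a per-day feature-engineering pipeline (24-hour
    summarisation, CKD-EPI 2021 eGFR, delta-from-median features, two-stage
    imputation, robust scaling), a model-training and evaluation harness with
    patient-grouped cross-validation and binned calibration, a rolling yearly
    framework simulation, and a synthetic ward-cohort generator with planted ground
    truth so every stage is testable without real hospital data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    pROC
Suggests:
    testthat (>= 3.0.0),
    ranger,
    xgboost,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
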