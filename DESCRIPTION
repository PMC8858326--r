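Package: edemapredict
Title: CT CSF Volumetrics and Recurrent-Network Prediction of Malignant Cerebral Edema
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying automated prediction of malignant cerebral
    edema after hemispheric stroke from serial head CT. Provides a synthetic
    cohort generator calibrated to published group statistics, a procedural
    head-CT phantom with known cranial/CSF/lesion/midline ground truth,
    CSF volumetric biomarker extraction (intracranial reserve, percent CSF
    change, hemispheric CSF ratio) with symmetry-based midline delineation,
    logistic, feed-forward and two-timestep LSTM classifiers under nested
    stratified cross-validation, precision-recall-centric evaluation with a
    paired stratified bootstrap comparison of AUPRC, and exact Shapley-value
    explanations of individual predictions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    RNifti,
    glmnet,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
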