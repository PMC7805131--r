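Package: ibmscore
Title: CT Imaging-Biomarker Survival Signatures for Oesophageal Cancer
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A tested re-implementation of a contrast-enhanced-CT
    imaging-biomarker (IBM) workflow for oesophageal-cancer survival
    analysis, exercised on synthetic CT-like cohorts.  Provides 3D
    radiomic feature extraction (96 features: intensity, geometry and
    GLCM/GLRLM/NGTDM/GLSZM texture families), a three-rule feature
    pre-selection cascade, LASSO-Cox signature construction with the two
    published scoring formulas frozen in code, time-dependent ROC with
    Youden-index risk stratification, Kaplan-Meier/log-rank evaluation,
    nomogram survival prediction and decision-curve analysis, plus a
    synthetic tumour-and-survival generator so the whole pipeline is
    testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    glmnet,
    igraph,
    jsonlite,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
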