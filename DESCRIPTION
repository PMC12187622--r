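Package: mrseries
Title: Metadata-Based Series-Type Identification and Curation for Prostate mpMRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies the series type (T2-weighted, diffusion-weighted,
    apparent diffusion coefficient, dynamic contrast-enhanced, or other) of
    prostate multiparametric MRI series from DICOM header metadata alone.
    Provides a lightweight DICOM Part 10 reader and writer, a four-step
    metadata sanitisation protocol with per-series unique-value aggregation,
    word n-gram tokenisation and numeric-string summary features,
    gradient-boosted five-class classifiers (an engineered-feature backend
    and a native-categorical backend) trained with nested stratified
    cross-validation and random hyperparameter search, leave-one-centre-out
    validation, learning curves with a two-step saturation detector, and
    five deterministic curation heuristics that pick the machine-learning
    ready axial T2W / high b-value DWI / plain ADC triplet from a study.
    A synthetic multi-centre DICOM fixture generator emulating vendor tag
    dialects makes the whole pipeline testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    xgboost (>= 2.0)
Suggests:
    arrow,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
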