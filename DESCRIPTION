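Package: agitsense
Title: Momentary Agitation Analysis of Wrist-Wearable Physiology in Dementia
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, testable pipeline relating wrist-worn sensor
    physiology (accelerometry, heart rate, electrodermal activity, skin
    temperature) to momentary observer-rated agitation in a dementia ward
    cohort. Provides per-modality signal quality control and preprocessing,
    electrodermal tonic/phasic deconvolution with a Bateman impulse response,
    six-minute survey-centered feature windows, within-patient
    standardization, and per-feature logistic generalized linear mixed
    models with a patient random intercept (Laplace approximation, with an
    adaptive Gauss-Hermite quadrature oracle for verification). Includes a
    fully synthetic ward-cohort generator that plants autonomic-activation
    signatures, so every stage of the analysis can be validated against
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    splines,
    jsonlite,
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    lme4
Config/testthat/edition: 3
RoxygenNote: 7.3.3
LinkingTo: Rcpp
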