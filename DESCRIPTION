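Package: cribmap
Title: Voxel-Wise Cribriform-Growth Probability Maps from Prostate ADC MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Patient-level prediction of cribriform Gleason-pattern-4 growth
    (GP4Crib+) in intermediate-risk prostate cancer from apparent diffusion
    coefficient (ADC) maps. Implements multi-scale sliding-window inference of
    a single-feature (90th-percentile ADC) logistic model with
    maximum-projection aggregation into whole-prostate probability maps,
    segmented IVIM fitting of multi-b-value diffusion MRI, slice-restricted
    prostate-mask erosion, bootstrap ROC/PR evaluation, and an active
    surveillance decision-scenario simulator with six-category over- and
    undertreatment accounting across Cambridge Prognostic Groups. Ships a
    synthetic phantom and cohort generator plus a fixed 127-record fixture
    cohort for end-to-end testing without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    RNifti,
    stats
LinkingTo: Rcpp
Suggests:
    ggplot2,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
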