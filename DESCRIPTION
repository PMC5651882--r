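Package: qusmap
Title: Quantitative Ultrasound Spectral Parametric Maps and Texture-Based
    Lesion Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative ultrasound (QUS) tissue characterization
    from beamformed radiofrequency (RF) data. Implements sliding-window
    spectral analysis with reference-phantom normalization and two-layer
    attenuation compensation to produce co-registered parametric maps of
    mid-band fit, spectral slope, spectral intercept, scatterer spacing
    (autoregressive Burg spectra normalized to a planar reflector), effective
    scatterer diameter and effective acoustic concentration (spherical
    Gaussian form-factor fits to the backscatter coefficient). Gray-level
    co-occurrence matrix (GLCM) texture features and mean-value biomarkers are
    extracted per map, aggregated per patient, compared between groups with
    Mann-Whitney U tests, combined by stepwise linear discriminant feature
    selection, and classified with a k-nearest-neighbour classifier under
    leave-one-patient-out cross-validation. A point-scatterer RF cohort
    simulator with known ground truth supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils,
    graphics
LinkingTo:
    Rcpp
Suggests:
    MASS,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
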