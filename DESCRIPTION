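Package: salspec
Title: Root-Zone Soil Salinity Estimation from Canopy Hyperspectral Reflectance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Chemometrics pipeline for estimating root-zone soil salinity
    (EC 1:5, dS/m) under vegetation cover from canopy hyperspectral
    reflectance (350-2500 nm) combined with plant growth parameters.
    Implements Savitzky-Golay smoothing and first-derivative preprocessing
    with noise-band trimming, wavelength selection by variable importance in
    projection (VIP), competitive adaptive reweighted sampling (CARS) and the
    random frog algorithm, NIPALS partial least squares regression with
    growth-parameter covariates and a stage-stratified calibration/validation
    split, and model evaluation by R-squared, RMSE and Lin's concordance
    correlation coefficient. Includes a synthetic data generator that
    emulates the salinity-growth-spectrum structure of a cotton amelioration
    field trial, so the full experiment grid can be exercised end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    optparse,
    yaml
Config/testthat/edition: 3
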