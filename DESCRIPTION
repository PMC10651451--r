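Package: spipls
Title: Chemometric Calibration of the Saliva Precipitation Index by PLS Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts the Saliva Precipitation Index (SPI, g/L gallic-acid
    equivalent) of red wines from physico-chemical parameters by partial least
    squares (PLS1, NIPALS) regression. Provides stratified train/test splitting,
    Cook's-distance outlier screening on the score regression, repeated
    randomized k-fold cross-validation, VIP-score and jack-knife coefficient
    significance for variable selection, a randomized permutation test for the
    number of latent components, overfitting control with Pareto knee detection,
    and export of portable raw-coefficient linear models. Includes a stratified
    synthetic wine-chemistry generator with known ground truth for benchmarking
    the full selection pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
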