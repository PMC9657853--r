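Package: spectroleaf
Title: Hyperspectral Waveband Selection and Nutrient Estimation for Leafy
    Greens
Version: 0.1.0
Authors@R:
    person("spectroleaf", "developers", email = "spectroleaf@example.org",
           role = c("aut", "cre"))
Description: An end-to-end chemometric pipeline for estimating nutrient
    status of hydroponically grown lettuce from visible/near-infrared
    hyperspectral images. Reads and writes ENVI-format reflectance cubes,
    extracts region-of-interest mean spectra, smooths them with a moving
    average and derives normalized-difference and first-derivative
    (red-edge style) spectra, detects dynamic waveband regions, fits
    NIPALS partial least squares (PLS1) and joint response-predictor PCA
    latent-variable models, selects informative wavebands by derivative
    regions, regression-coefficient peaks, or variable-importance-in-
    projection (VIP) scores, and evaluates fitted multivariate regressions
    with R-squared, RMSE, and band-windowed Pearson cross-correlation.
    Includes a fully specified synthetic-data generator with known ground
    truth so every stage is testable without proprietary cubes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
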