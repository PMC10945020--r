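Package: hsiATP
Title: Hyperspectral Chemometrics for Non-Invasive ATP Estimation in Sausages
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for estimating adenosine triphosphate (ATP) content in
    processed meat from visible/near-infrared hyperspectral images.
    Implements reflectance calibration against dark and white references,
    threshold segmentation and equal-area cross-section partitioning of
    sausage images, a spectral pre-treatment library (absorbance, standard
    normal variate, multiplicative scatter correction, min-max
    normalisation, Savitzky-Golay smoothing, increment derivatives) with
    leakage-safe fit/apply chains, Kennard-Stone sample-set partitioning,
    partial least squares regression with full (leave-one-out)
    cross-validation, pixel-wise ATP distribution maps, and a central
    composite design response-surface analysis linking casing-treatment
    factors to ATP. A synthetic scene generator with known ground truth
    makes every stage testable without camera data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    jsonlite,
    png,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
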