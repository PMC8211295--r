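Package: soilscape
Title: Spatio-Temporal Analysis of Soil Microbial Communities Across a
    Farmed Landscape
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for landscape-scale, two-campaign analyses of soil
    microbial communities under changing farming practices: a synthetic
    landscape generator with known ground truth, a daily two-compartment
    soil water-balance model yielding cumulative water-stress days,
    crop-rotation and farming-intensity indicators (treatment frequency
    indices, rotation frequencies, fertilizer loads), rank-order
    (normal-score) ordinary kriging with Matern variograms fitted by
    weighted nonlinear least squares and validated by leave-one-out
    standardized errors, and a partial least squares path-modeling engine
    (mode A, centroid/factorial/path schemes) with effect decomposition,
    goodness of fit, bootstrap validation and architecture comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
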