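Package: hsmad
Title: Adaptive Detection of Plasmonic Nanoparticles in Hyperspectral
    Dark-Field Microscopy Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and quantifies metallic nanoparticles in hyperspectral
    dark-field images of histological tissue sections. Implements the full
    adaptive-detection workflow: ENVI cube input/output with lamp
    normalization, cosine-fourth vignetting correction, adaptive
    histogram-based segmentation into background/tissue/candidate pixels,
    k-means learning of a spectral cluster library (with a manually added
    chromatic-aberration cluster), nearest-centroid and spectral-angle-mapper
    per-pixel classification, biodistribution quantification (relative
    nanoparticle signal and pixel coverage over regions of interest),
    diagnostic statistics with log-method confidence intervals, a
    point-spread-function consistency check for single-particle detection,
    false-color rendering, and a fully synthetic phantom generator with
    ground-truth masks for end-to-end benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    signal,
    stats,
    tiff,
    tools,
    utils
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
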