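Package: angiovis
Title: Vessel Visibility Enhancement for X-Ray Coronary Angiograms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Enhances the visibility of coronary blood vessels and
    interventional tools in X-ray angiogram frames. A fixed-size oriented
    Gabor bank applied over a Gaussian image pyramid extracts multiscale
    edge responses, a visual-cortex-inspired lateral-facilitation operator
    performs collinear line completion with simultaneous noise suppression,
    per-scale Otsu masks fused by sliding medians delineate the blood-vessel
    region of interest, and a dynamic-range-balanced blend integrates the
    completed edge texture back into the frame. Ships a seeded synthetic
    angiogram phantom generator with ground-truth masks and contrast-to-noise
    evaluation utilities, plus a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    EBImage,
    igraph,
    png,
    tiff,
    yaml,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
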