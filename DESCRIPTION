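Package: octmelanin
Title: Melanin Morphometry and Speckle Denoising for Cellular-Resolution OCT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies melanin morphology in cellular-resolution full-field
    optical coherence tomography (FF-OCT) skin images. Provides spatial
    compounding of adjacent B-scan slices into clean/noisy training pairs, a
    residual-learning convolutional denoiser for multiplicative speckle,
    rule-based segmentation of hyper-reflective melanin into grain and
    confetti classes (exponential contrast-limited adaptive histogram
    equalization, brightness thresholding, binary morphology and size gates),
    extraction of 18 per-image morphometric features, and layer-stratified
    two-sample statistics comparing lesion against perilesional cohorts. A
    seeded synthetic FF-OCT simulator with known melanin ground truth makes
    the whole pipeline testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    igraph,
    jsonlite,
    nortest,
    png,
    stats,
    tiff,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
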