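Package: stainmux
Title: Multiplexed and Micro-Structured Virtual Histological Staining
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: A class-conditional adversarial image-to-image framework that
    renders virtually stained bright-field images of label-free tissue from
    two autofluorescence channels (DAPI-like and Texas-Red-like). A per-pixel
    digital staining matrix conditions a single U-net generator so that one
    trained network produces several histological stains (H&E, Masson's
    trichrome, Jones' silver), blends them at arbitrary ratios, and applies
    different stains to user-drawn regions of interest within one tissue
    section. Includes elastic pyramidal block-matching co-registration of the
    input channels, coarse cross-correlation alignment of bright-field
    targets, whole-slide normalization and patch extraction, whole-patch SSIM
    and YCbCr difference metrics, and a seeded synthetic phantom generator
    with deterministic per-stain oracle renderings for end-to-end testing.
License: MIT
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    jsonlite,
    yaml,
    tiff,
    png,
    EBImage
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
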