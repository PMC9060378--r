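Package: segsynth
Title: Single-Image Generative Synthesis of Segmentation Image-Mask Pairs
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Trains a multi-scale generative adversarial network on a single
    image and its binary segmentation mask, stacked as a four-channel sample,
    so that new image/mask pairs are synthesized jointly.  A neural style
    transfer refinement step transfers texture from the real image onto
    generated images.  Includes Frechet-distance evaluation machinery (FID
    and single-image FID over spatial features), mask-distribution
    statistics, a procedural lesion-like fixture generator, and a command
    line interface covering the train, generate, refine and evaluate
    pipeline.  All networks run on the CPU in plain R; no pretrained weights
    are required for any test path.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    optparse,
    png,
    stats,
    utils,
    yaml
Suggests:
    callr,
    jpeg,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
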