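Package: hipscreen
Title: Graf-Method Infant Hip Ultrasound Screening with Landmark
    Segmentation and Decision Support
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A testable re-implementation of an AI-aided screening workflow
    for developmental dysplasia of the hip (DDH) from cine-sweep ultrasound.
    Provides a parametric synthetic phantom generator for coronal Graf-plane
    hip frames with exact ground-truth geometry, a small U-Net-style
    convolutional segmenter for the acetabulum-ilium complex and femoral
    head trained with a DICE loss, Graf geometric measurement (acetabular
    alpha angle and femoral head coverage) from label masks via total
    least-squares line fitting and algebraic circle fitting, frame-adequacy
    gating with a capture loop and a three-way clinical decision heuristic,
    and screening-program statistics (cohort category summaries, referral
    confirmation rate, rolling follow-up-rate learning curves).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
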