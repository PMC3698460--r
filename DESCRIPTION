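Package: spindex
Title: Scribble Perseveration Index for Cancellation-Task Drawings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Retrospective quantification of continuous motor perseveration
    from scanned cancellation-task scribbles. Computes the Scribble
    Perseveration Index (SPI), a proxy for the number of elementary pen
    movements (strokes or loops) composing a scribble, from three image
    measurements: ink area, pen-trace thickness, and a linear size selected
    by a direction flowchart over Feret diameters. Includes maximum-entropy
    binarization, skeleton and distance-transform morphometry, a pen
    trajectory simulator with known ground-truth movement counts, and a
    validation harness reporting correlation and regression of SPI against
    the true movement count.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    png,
    tiff,
    jsonlite,
    stats,
    tools,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
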