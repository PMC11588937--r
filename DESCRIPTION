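Package: rusitrack
Title: Automated Contraction Assessment of Abdominal Muscles from Ultrasound Video
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying abdominal-muscle contraction in rehabilitative
    ultrasound imaging (RUSI) video. Provides propagation of segmentation masks
    through a video by pyramidal Lucas-Kanade optical flow with correlation-based
    reference-frame selection, automated muscle thickness and lateral
    center-of-mass measurement from label masks, a percentile-based
    distribution-overlap statistic with calibrated thresholds for classifying
    muscles as contracted or relaxed, a simulated real-time blockwise assessment
    mode, Dice-based evaluation utilities, and a synthetic speckle-phantom
    generator emulating the rest-exercise-rest acquisition protocol so that the
    whole pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    graphics,
    jsonlite,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
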