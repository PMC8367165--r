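Package: woundqc
Title: Acquisition-Time Quality Control for Wound Photographs with a Color Reference Sticker
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for automated quality assessment of wound photographs taken
    with a square 36-patch color reference sticker in the field of view.
    Implements sticker detection by rectangular morphology, a
    variance-of-Laplacian sharpness score restricted to the sticker region of
    interest, and a pass/retake quality gate suitable for acquisition-time
    feedback. Also provides the accompanying study analysis layer (color
    checker detection ratio, sharpness summaries, subjective-usability ratios,
    compliance, duration outlier filtering, rank-sum group comparison, duration
    trends) and a deterministic synthetic scene and cohort generator that
    supplies ground truth for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    stats,
    utils,
    grDevices,
    rlang,
    tibble,
    dplyr,
    readr,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
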