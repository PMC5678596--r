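Package: dielpheno
Title: Diel Plant Growth Phenotyping from Top-View VIS/NIR Time-Lapse Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Segmentation and growth-trait extraction for top-view time-lapse
    imaging of Arabidopsis rosettes across the full 24-h diel cycle. Light-period
    RGB (VIS) frames are segmented by per-channel range thresholding in RGB, HSV
    or CIE Lab colour space (or grayscale Otsu); dark-period near-infrared (NIR)
    frames are segmented with a two-region Chan-Vese active contour initialised
    from the adjacent VIS mask and propagated frame to frame, forward and in
    reverse, with the two passes averaged. Includes uneven-illumination
    correction for single-channel frames, stable left-to-right or user-seeded
    plant labelling, projected rosette area (PRA) and relative expansion rate
    (RER) computation (daily endpoints and 10-frame sliding-median diel series),
    and a synthetic scene generator with per-frame ground truth for validating
    the whole pipeline without real imagery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    grDevices,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tiff,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
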