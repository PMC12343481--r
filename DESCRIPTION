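Package: pocketcav
Title: Quantification of Laser-Induced Cavitation and Bacterial Removal in
    Periodontal Pocket Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Image-analysis pipeline for Er:YAG laser-induced photoacoustic
    cleaning experiments in zero-gap periodontal pocket models. Provides
    two-stage segmentation of primary bubbles and secondary cavitation from
    high-speed video frame sequences, calibrated area time series and
    per-pulse statistics, dual-pulse delay-sweep analysis, counting of
    crystal-violet-stained bacterial monolayers with quadrant statistics,
    frame-pair particle velocimetry, and shared laser/material physics
    utilities. Includes seeded synthetic phantom generators (cavitation
    videos, stained-monolayer micrographs, particle displacement pairs)
    with exact ground truth for validating every stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    pracma,
    stats,
    grDevices,
    tiff,
    png,
    yaml,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    ggplot2,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
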