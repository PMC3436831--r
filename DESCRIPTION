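Package: colonytrack
Title: Quantification and Visualization of Stem Cell Colony Dynamics in
    Time-Lapse Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated quantification of spatio-temporal patterning in
    stem-cell colony time-lapse sequences. Estimates dense inter-frame
    displacement fields by a curvature-regularized fluid image
    registration, segments colonies in phase-contrast frames (retinex
    illumination correction, total-variation denoising, region-based
    active contours), tracks colonies across frames by label propagation
    with explicit merge/split handling, computes per-colony structural
    and dynamical statistics (area, elongation, circularity, gray-level
    entropy, internal displacement), and renders colony lineages as a
    stream-style visualization. Includes a synthetic sequence generator
    with analytic ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
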