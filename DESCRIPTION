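Package: spherotax
Title: Quantification of Electrotaxis in Spheroid Invasion Assays and
    Single-Cell Tracks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify directed cell migration (electrotaxis) under
    direct-current electric fields, for both single-cell tracks and 3D
    spheroidal aggregates invading a matrix. Implements field-setting
    arithmetic and current-log quality control, scalar-projection track
    statistics, translation-only image registration, aggregate segmentation,
    four-frontier (cathodal, anodal, orthogonal, orthogonal-prime) extraction
    with cathodal/orthogonal bias and bounding-box area-change metrics, the
    accompanying group statistics (Student t-test, two-factor ANOVA with
    Holm-Sidak post-hoc, Benjamini-Hochberg adjustment), RNA-seq
    post-processing into pre-ranked gene lists, and seeded synthetic-data
    generators for every input so the whole pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    readr,
    yaml,
    stats,
    EBImage,
    car,
    emmeans,
    withr
Suggests:
    testthat (>= 3.0.0),
    png,
    tiff,
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
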