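Package: flystrip
Title: Strip-Based Quantification of Gene Expression Boundaries in Fly Embryo Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A medium-throughput pipeline for processing colorimetric whole-mount
    in situ hybridisation (WMISH) images of dipteran embryos into quantitative
    gene expression domain boundaries. Segments single embryos from 10x DIC
    micrographs with a morphological mask pipeline, orients them along the
    antero-posterior axis using image moments, extracts graded expression
    profiles from a 10% dorso-ventral strip around a skeleton-derived midline
    spline, fits clamped cubic splines to expression domain boundaries, and
    aggregates median boundary positions across embryos and developmental time
    classes. Includes a synthetic embryo image generator with exact ground
    truth, a plain-text batch store, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml,
    withr
Suggests:
    EBImage,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
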