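Package: cfcquant
Title: Quantification of Myogenic Colony-Forming-Cell Assays from
    Two-Channel Fluorescence Micrographs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Counts nuclei in DAPI-stained (blue channel) fluorescence
    micrographs of satellite-cell colonies, resolving clumps of overlapping
    nuclei through a dataset-wide size calibration of the DAPI+ area
    histogram, detects sarcomeric myosin heavy chain (MHC) positive
    cytoplasm in the red channel, and maps nuclear centroids into MHC+
    regions to compute per-colony proliferation and differentiation
    metrics: total nuclei, the coefficient of differentiation (Df) and the
    fusion index (Ui). Includes a deterministic synthetic-colony generator
    with exported ground truth, batch processing over image directories
    with CSV output and overlay renderings, and group-level statistical
    summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    EBImage,
    dplyr,
    generics,
    ggplot2,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils
Suggests:
    optparse,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
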