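Package: tmespatial
Title: Spatial Analysis of Tumor-Infiltrating Immune Cells in Multiplexed Imaging Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for spatial profiling of tumor-infiltrating immune cells
    from multiplexed immunohistochemistry cell maps. Provides threshold-based
    phenotype gating from per-cell marker intensities, density and proportion
    profiling across tumor-core / invasion-margin / normal tissue compartments,
    radius-based neighborhood pairing with effective-score and average-distance
    statistics, per-region cell-count correlation networks, nonparametric and
    parametric group comparisons, and a synthetic tumor-slide simulator
    (Poisson background plus Thomas-style attraction processes) for
    validation and power exploration.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    generics,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
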