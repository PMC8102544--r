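Package: vfsector
Title: Sector-Wise Trend Analysis and Forecasting of Humphrey 10-2 Visual Fields
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for sector-based analysis of Humphrey Field Analyzer 10-2
    visual fields in retinitis pigmentosa. Derives data-driven sector maps of
    the 68-point grid by HOPACH-PAM clustering (partitioning around medoids
    with median-split-silhouette model selection) of total-deviation values,
    forecasts future fields by sector-wise trend regression alongside
    pointwise linear regression and global-mean regression, and compares
    forecast accuracy by mean absolute error using linear mixed models with
    Benjamini-Hochberg multiplicity correction. Ships reference sector maps,
    a longitudinal cohort CSV format, and a synthetic cohort generator that
    emulates progressive concentric field loss with perimetric noise.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    lmerTest,
    yaml
Suggests:
    testthat (>= 3.0.0),
    cluster,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
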