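Package: tissuemaps
Title: Quantitative Tissue-Map Analysis and Prognostic Scoring for
    Non-Small Cell Lung Cancer Histopathology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-processing and quantification layer for multi-class
    tissue segmentation masks of non-small cell lung cancer whole-slide
    images. Provides an 11-class (+ background) tissue legend, exact
    per-class area profiling, a tile-based inference harness with
    pluggable segmenters, per-class Dice validation against annotated
    ground truth, area-percentage LUAD/LUSC subtyping with a borderline
    zone and mucin fraction, four explainable prognostic parameters
    (TLS tumor density, necrosis tumor density, TLS/necrosis ratio and
    a cumulative three-level prognostic group) with optimal-cutpoint
    survival stratification, Kaplan-Meier/log-rank/Cox machinery, and a
    synthetic mask and cohort generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
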