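Package: cellmon
Title: Label-Free Cell-Culture Monitoring and Quality Control from Relief-Contrast Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A toolkit for automated quality control of adherent cell
    cultures imaged label-free with oblique (relief-contrast) illumination.
    Provides a plate/well/region acquisition data model, a synthetic image
    generator with exact ground truth, cell segmentation with counting and
    confluency, per-cell morphometrics (projected area, circularity), growth
    curves and doubling-time estimation, skeleton-graph quantification of
    capillary-like networks, microwell spheroid-formation tracking, and
    rule-based culture quality flagging.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    Rcpp,
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
    grDevices,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
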