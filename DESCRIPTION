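Package: pavasc
Title: Depth-Resolved Vascular Morphometry for Photoacoustic Breast Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of three-dimensional photoacoustic breast
    volumes after autologous fat grafting: skin-surface detection and probe
    contact quality control, periareolar region-of-interest extraction,
    depth-stratified vascular density at 2.5 mm layers, automated vessel
    diameter measurement by skeletonisation and distance transform,
    quartile-anchored caliber classification, and postoperative-interval trend
    analysis of caliber proportions. Includes a synthetic paired-breast
    vascular phantom generator with known ground truth so the whole pipeline
    is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    tiff,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    ggplot2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
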