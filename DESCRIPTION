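Package: tavisize
Title: Automated Aortic Annulus Measurement and TAVI Device Size Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated measurement of the aortic annulus from 2-D
    contrast-enhanced CT annular-plane images and transcatheter aortic
    valve implantation (TAVI) prosthesis size selection. Implements a
    dual-resolution encoder-decoder residual segmentation network trained
    on binary annulus masks, probability-map fusion, canny-based contour
    extraction with planimetric area and perimeter measurement, and
    sizing-chart lookup for area-sized (Edwards Sapien 3) and
    perimeter-sized (Medtronic Evolut) devices. Includes a synthetic
    annular-plane phantom generator with exact analytic ground truth and
    the full interobserver agreement battery (Dice coefficient, paired
    Wilcoxon signed-rank differences, Pearson correlation, Shapiro-Wilk,
    Bland-Altman limits of agreement, and device-size agreement ratios).
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    png,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    mgcv,
    pracma,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
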