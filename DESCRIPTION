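Package: nodulite
Title: Lightweight Lung-Nodule Detection with Omni-Dimensional Attention Convolution
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale re-implementation of a lightweight single-stage lung-nodule
    detector for thoracic CT. Provides omni-dimensional dynamic convolution (ODConv)
    blocks with four-way attention, a weighted bidirectional feature-pyramid neck built
    from lightweight GSConv layers, and a combined Focal + normalized-Wasserstein-distance
    (F-NWD) objective for tiny-nodule box regression, assembled on a CSP-style single-class
    detector. Includes a MetaImage (.mhd/.raw) reader/writer, lung-parenchyma segmentation,
    world-to-pixel annotation conversion, a synthetic CT-phantom generator emulating
    LUNA16-shaped data, CPU training at reduced scale, and precision/recall/mAP evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    readr,
    stringr,
    png,
    yaml,
    jsonlite,
    EBImage,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
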