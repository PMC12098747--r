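Package: vistain
Title: Virtual Hematoxylin-and-Eosin Staining of Label-Free Refractive-Index Volumes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for computational ("virtual") hematoxylin-and-eosin staining
    of label-free refractive-index (RI) image stacks from quantitative phase
    imaging. Implements the full desk-scale pipeline: all-in-focus compositing
    of focal stacks by windowed normalized variance, affine registration of
    stained brightfield images onto label-free images by minimizing a Pearson
    correlation loss, curation of co-registered training patches, a conditional
    generative adversarial network with a correlation-based reconstruction term
    that learns the RI-to-RGB stain mapping, overlap tiling with feathered
    stitching for wide-field inference, and a quantitative validation suite
    (band-limit matching, RGB structural similarity, Jaccard overlap, and 2D/3D
    nuclear and glandular morphometrics). A synthetic phantom generator
    provides paired (RI, H&E) images with known ground truth so every stage is
    testable without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    png,
    Rcpp,
    stats,
    tibble,
    tiff,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
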