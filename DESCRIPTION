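Package: octlayers
Title: Cascaded Compressed U-Net Segmentation of Intraretinal Layers in Macular OCT
Version: 0.1.0
Authors@R:
    person("OCT", "Segmentation Lab", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Fully automated intraretinal layer segmentation of macular optical
    coherence tomography (OCT) B-scans using a cascade of two compressed U-Net
    networks: a retina-segmentation stage (3 classes) whose output joins the
    image as the second input channel of an intraretinal stage (9 classes).
    Includes the weighted focal loss used to counter foreground-background
    pixel imbalance, surface postprocessing (adaptive hole filling, Laplacian
    outlier rejection, shape-preserving PCHIP infill, 3x3 smoothing, anatomical
    ordering), evaluation metrics (Dice, boundary MAE, macular thickness and
    volume parameters, one-way-ANOVA ICC), and a synthetic OCT phantom
    generator with exact ground truth so the whole pipeline is trainable and
    testable without clinical data. The network engine (im2col convolutions,
    backpropagation, Adam) is self-contained on RcppArmadillo.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    png,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    rhdf5,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
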