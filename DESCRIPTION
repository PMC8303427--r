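Package: echograph
Title: Graph-Constrained Convolutional Classification of Echocardiographic Views
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies standard transthoracic echocardiographic views with a
    convolutional network regularized by a mutual-information similarity graph
    over the training images. A spatial-transformer module learns an affine
    alignment that reduces cardiac-cycle deformation, a squeeze-and-excitation
    block recalibrates channel responses, and an unsupervised graph loss pulls
    embeddings of similar images together. Includes a synthetic echo-like image
    generator, subject-wise preprocessing and splitting, graph construction,
    training with early stopping, and one-vs-rest evaluation metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    png,
    jsonlite,
    Rcpp,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
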