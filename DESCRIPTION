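Package: grnimage
Title: Supervised Gene Regulatory Network Inference from Image-Encoded
    Single-Cell Co-Expression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Infers cell-type-specific gene regulatory networks from
    single-cell RNA-seq by rendering the joint expression of each candidate
    transcription-factor/target pair as a 32x32 two-dimensional histogram
    image, surrounding it with covariance-ranked neighbor images, and scoring
    the directed pair with a twin residual convolutional network trained on
    known TF-target interactions. Includes the full preprocessing chain
    (per-cell normalization, log transform, highly-variable-gene selection,
    per-gene winsorization), a self-contained convolutional network engine
    with seeded SGD training and early stopping, stratified k-fold
    cross-validation with AUROC evaluation, dropout-noise robustness and
    neighbor-count sweeps, and a synthetic single-cell data generator with
    planted regulatory edges and transitive-chain confounders.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
LinkingTo:
    Rcpp,
    RcppArmadillo
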