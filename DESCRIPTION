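Package: scAVAE
Title: Adversarial Variational Autoencoders for Single-Cell RNA-Seq
    Dimensionality Reduction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Reduces single-cell RNA-seq count matrices to a low-dimensional
    latent space with an adversarial variational autoencoder with dual
    matching (AVAE-DM). The decoder reconstructs counts under a
    zero-inflated negative binomial (ZINB) likelihood; a latent-space
    discriminator matches the variational posterior to a standard normal
    prior and an optional data-space discriminator matches reconstructions
    to the real expression distribution. Four interchangeable adversarial
    objectives are provided (standard GAN, Wasserstein, Wasserstein with
    gradient penalty, and a Bhattacharyya-distance objective). Includes
    count-matrix readers (MatrixMarket and dense CSV/TSV), the standard
    preprocessing protocol (top-variance gene selection, log2(1+C)),
    a ZINB simulator with planted cluster structure, K-means/NMI clustering
    evaluation, 2-D visualization helpers, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    Rtsne,
    uwot
Config/testthat/edition: 3
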