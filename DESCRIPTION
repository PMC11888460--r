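Package: casdesign
Title: Margin-Regularized Transformer Autoencoder for CRISPR-Cas Protein Design
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Generative design of CRISPR-associated (Cas) nuclease proteins
    with a transformer-encoder / 1-D convolutional-decoder autoencoder whose
    latent space is regularized by a classification loss and a max-margin
    loss. A Gaussian-process Bayesian-optimization loop proposes latent
    vectors, gates them through a Cas/non-Cas classifier, decodes them to
    amino-acid sequences, scores them with a pluggable structure oracle, and
    filters them for novelty by local-alignment percent identity against a
    reference database. Includes a seeded synthetic protein-family simulator
    so the whole pipeline is trainable and testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    S4Vectors,
    cluster,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
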