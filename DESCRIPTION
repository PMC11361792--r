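Package: rnaloc
Title: Multi-View Multi-Label Prediction of mRNA Subcellular Localization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Predicts the subcellular localization of mRNA transcripts across
    six human compartments (nucleus, exosome, cytosol, ribosome, membrane,
    endoplasmic reticulum) as a multi-label classification problem. Fuses two
    views of each transcript: primary-sequence composition encodings (k-mer
    and k-spaced nucleic acid pair frequencies) processed by multilayer
    perceptron plus multi-head self-attention branches, and secondary-structure
    graphs built from dot-bracket notation processed by graph isomorphism
    network branches with set2set readout. Includes a dependency-free
    maximum-base-pairing fallback folder, an adapter for external structure
    prediction tools, six multi-label evaluation metrics, edge-mask model
    interpretation with substructure extraction, and a fully seeded synthetic
    benchmark generator with planted sequence motifs and hairpin elements.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    Biostrings,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
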