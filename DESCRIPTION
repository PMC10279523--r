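Package: omicsGCN
Title: Multi-Omics Cancer Subtyping with a Multi-Reconstruction Graph
    Convolutional Autoencoder
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Integrates full or partial multi-omics patient data into a
    shared latent embedding by jointly reconstructing each omics layer's
    expression matrix and its sample-similarity graph with per-omics graph
    convolutional encoders and decoders. Patients missing whole omics
    layers are handled without imputation through binary indicator
    matrices that align each omics to the intact patient universe.
    Cluster assignments are refined by deep-embedded-clustering style
    KL self-supervision and patients are partitioned into subtypes by
    eigengap-guided spectral clustering of the consensus embedding.
    Includes a synthetic multi-omics generator with planted cluster
    structure for validation, clustering-quality metrics, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    cluster,
    mclust,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
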