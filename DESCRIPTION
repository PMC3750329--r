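Package: genoanat
Title: Genetic Neuroanatomy of Voxel-Level Gene Expression Atlases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying the concordance between spatial gene
    expression and hierarchical neuroanatomy in voxel-gridded brain
    atlases. Provides an exact t-distributed stochastic neighbor
    embedding (t-SNE) implementation with per-point perplexity
    calibration, a centered-PCA baseline, k-means parcellation with a
    restart protocol, and class-to-cluster consistency measures (NMI,
    ARI, purity, S-index) evaluated against a level-numbered anatomical
    ontology. A seeded synthetic-atlas generator emulates a developing
    brain annotated with a grid of transversal segments and longitudinal
    zones, so the full pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
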