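Package: pathcg
Title: Transition Pathways of Two-State Proteins from Coarse-Grained
    Metadynamics and Contact-Map Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying large conformational changes of proteins
    that adopt two experimentally resolved states.  The package builds
    dual-basin C-alpha structure-based (Go-type) models from a pair of
    structures, runs Langevin dynamics with well-tempered metadynamics
    over the two RMSD collective variables to estimate a 2D free-energy
    surface, locates the lowest-barrier transition pathway with a
    two-round search (nudged elastic band plus stochastic grid walks),
    featurizes structures as sigmoid-transformed C-alpha distance
    matrices, trains a residual convolutional network to predict the
    distance matrix of the high-energy (transition) state and of two
    flanking intermediates, and reconstructs C-alpha structures along
    the predicted pathway by restrained simulated annealing.  Includes
    dataset-curation rules for multi-state versus single-state proteins,
    contact-type frequency statistics, and synthetic fixtures (toy
    two-state hinge proteins, analytic landscapes, rule-based training
    corpora) with independent brute-force oracles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    bio3d,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
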