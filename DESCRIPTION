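Package: neuroconf
Title: Branch-Confidence Artifact Detection for Neuron Reconstructions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Detects reconstruction artifacts in neuron morphologies (SWC)
    by scoring every branch with a connection confidence derived from a
    Markov-chain model of parent-child branching segments. Branch energies
    combine intensity mean, intensity standard deviation and branching
    angle measured in the source 3D image stack; unreconstructed signal is
    recovered as skeleton branches via enhancement, binarization, 3D
    thinning and Frangi vesselness. Branches are classified as over-traced,
    misconnected (branch-skeleton or branch-branch), missing or incompletely
    traced, supporting an iterative detect-modify proofreading workflow.
    Includes a deterministic synthetic-fixture generator and standard
    reconstruction-versus-ground-truth metrics (precision/recall/F1,
    ESA/DSA/PDS).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tiff,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
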