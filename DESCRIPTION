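Package: deeppotr
Title: Deep Potential Neural-Network Interatomic Potentials
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Desk-scale implementation of the Deep Potential family of
    neural-network interatomic potentials: smooth atomic-environment
    descriptors (local-frame, two- and three-body embedding, attention-based,
    hybrid), energy and tensor fitting heads with analytic forces and virials,
    an Adam trainer with an exponentially decaying learning-rate schedule and
    composite energy/force/virial losses, ensemble model deviation for
    concurrent-learning candidate selection, quintic tabulation-based model
    compression, QM/MM range correction, reciprocal-space long-range
    electrostatics, and pairwise-potential interpolation.  Includes a
    Lennard-Jones synthetic-data generator and a command-line interface so the
    whole pipeline is testable end to end without external datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
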