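Package: nccm
Title: Differential Gene Screening by Logic-Network Control Capability
Version: 1.0.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Constructs first-order logic networks from two-group gene
    expression data with an information-theoretic procedure (entropy, mutual
    information, uncertainty coefficient), scores every gene's control
    capability as the rank of its single-input Kalman controllability matrix
    computed by a Krylov-subspace method, and screens differential control
    capability genes (DCCGs) between the two groups across a weight-threshold
    sweep. A degree-difference comparator and a synthetic two-group expression
    simulator with a planted set of rewired edges are included for
    benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite,
    yaml,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
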