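Package: eesprofiler
Title: Efficient Enantioseparation Profile Prediction for Chiral HPLC
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting Efficient Enantioseparation (EES) versus
    mobile-phase profiles in chiral HPLC. Implements the retention-penalized
    EES metric with its practical rules and penalty-factor simulation, a
    penalized multi-subset quality objective for artificial neural network
    (ANN) model selection, a chaotic competitive-learning population optimizer
    that jointly searches data splits, network topologies and descriptor
    subsets, and a median/MADe consensus model that emits full EES
    mobile-phase profiles with robust uncertainty and feasibility calls.
    Includes a seeded synthetic-data generator emulating chiral
    chromatographic screening data, CSV I/O for descriptor and
    chromatographic tables, model serialization, and a pipeline runner with
    provenance manifests.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    yaml,
    Rcpp,
    stats,
    utils,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
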