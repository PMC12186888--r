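Package: rhodrift
Title: Stochastic Simulation and Inference of Biased Mitochondrial DNA
    Inheritance in Heteroplasmic Yeast
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying the biased inheritance of deletion-bearing
    (rho-) mitochondrial DNA in Saccharomyces cerevisiae. Provides an
    agent-based stochastic simulator of mtDNA drift and two-level selection
    in growing populations of heteroplasmic cells, a simulation-grid
    k-nearest-neighbour estimator of intracellular mtDNA fitness from
    suppressivity assays, coverage-based mtDNA/nDNA copy-number estimation
    from per-base depth profiles, maximum specific growth rate estimation
    from plate-reader optical density curves, suppressivity assay
    statistics, and a synthetic-data generator that emulates the
    statistical structure of all of these inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    jsonlite,
    IRanges
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
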