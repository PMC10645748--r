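Package: kvclust
Title: Ion-Channel Cluster Assembly, Quantal Sparklet Activity, and
    Current-Density Scaling in Arterial Myocytes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying the spatial organization and activity of
    voltage-gated ion channels (KV2.1, CaV1.2) in the plasma membrane of
    arterial smooth muscle cells. Provides a stochastic lattice model of
    cluster self-assembly by nucleation, growth, and removal; segmentation
    of clusters from 3D confocal stacks and 2D super-resolution
    localization maps with exponential size-distribution fitting and a
    macro/micro cluster classification; quantal analysis of Ca2+ sparklet
    traces including site activity (nPs) and coupling-coefficient (kappa)
    estimation under a coupled Markov chain; linear functional-fraction
    scaling of whole-cell current densities with drug-subtraction IV
    analysis; and synthetic-data generators with known ground truth for
    every input the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    tiff,
    igraph,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
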