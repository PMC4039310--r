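Package: oncoint
Title: Mutant-EGFR Interactome Perturbation Analysis
Version: 0.1.0
Authors@R:
    person("Maintainer", "oncoint", email = "oncoint@example.org", role = c("aut", "cre"))
Description: Assembles bait-prey interactomes from tandem affinity
    purification mass spectrometry (TAP-MS) peptide evidence, scores
    drug-induced phosphosite perturbation from spectral counts with a
    chi-squared product statistic, extends networks through reference
    protein-protein interactions, identifies multi-cell-line core
    dependency networks from RNAi viability screens with rank-sum
    specificity testing, filters drug-target databases by binding
    affinity and ranks compounds by network diffusion, and quantifies
    drug-pair synergy with median-effect fits and the Chou-Talalay
    combination index. Every input can be simulated with planted ground
    truth for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
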