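Package: recombgs
Title: Genomic Selection Simulation with Engineered Recombination Landscapes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Stochastic simulation of doubled-haploid wheat breeding programs
    under modified meiotic recombination. Provides a synthetic founder
    generator with tunable coupling/repulsion linkage structure and
    pericentromeric deleterious-variant enrichment, a gamma-renewal meiosis
    engine with crossover interference, genetic-map scaling by recombination
    treatment (wildtype, pericentromere, whole chromosome; 2- or 20-fold),
    additive trait architectures with effect-sign scenarios, ridge-regression
    BLUP genomic prediction with genome-wide or causal-variant predictor
    sets, a burn-in plus 10-cycle genomic-selection scheme with
    training-population bookkeeping, per-cycle response variables (additive
    and genic variance, Bulmer ratio, genetic gain, prediction accuracy, QTL
    fixation and allele-frequency change), and a factorial experiment layer
    with ANOVA variance decomposition and marginal means.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    parallel,
    car
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
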