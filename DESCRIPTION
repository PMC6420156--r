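Package: crocker
Title: Topological Model Selection for Collective Motion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation and model selection for collective insect motion.
    Implements two stochastic random-walk models of pea aphid movement in a
    circular arena (an interactive model whose transition probabilities, step
    lengths and turning-angle spread depend on nearest-neighbour distance, and
    a non-interacting control model), collective-motion order parameters
    (polarization, angular momentum, absolute angular momentum, mean
    nearest-neighbour distance, percent moving), and topological trajectory
    signatures: Betti numbers of Vietoris-Rips complexes over a time-by-scale
    grid ("crocker" matrices), computed from scratch via persistent homology
    over the two-element field. Model preference against a reference
    trajectory is decided from ensembles of simulations with Euclidean /
    Frobenius distances and Bonferroni-corrected confidence intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
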