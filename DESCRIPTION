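Package: CoTransFold
Title: Deterministic Simulation of Cotranscriptional RNA Folding Kinetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates how the secondary-structure ensemble of an RNA molecule
    changes while it is being transcribed. For every newly transcribed
    nucleotide a sparse energy landscape of candidate structures is expanded
    by constrained minimum-free-energy folding around the exterior loop, a
    guide-graph neighborhood supplies candidate reactions whose saddle
    energies are estimated with a direct-path (findpath-style) search and a
    one-dimensional flooding procedure, the landscape is coarse-grained into
    delta-minimum representative structures, occupancies are propagated by
    integrating the master equation via symmetrized eigendecomposition, and
    low-occupancy representatives are pruned after a look-ahead simulation.
    Free energies come from the nearest-neighbor model of the ViennaRNA
    library, against which the package links. A stochastic elementary-move
    (Gillespie) simulator with Metropolis rates is included as an independent
    reference for validation on short sequences.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Matrix,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
SystemRequirements: ViennaRNA RNAlib (>= 2.5), GNU make
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'RcppExports.R'
    'structures.R'
    'energy-model.R'
    'path-search.R'
    'expansion.R'
    'coarse-grain.R'
    'kinetics.R'
    'pruning.R'
    'transcribe.R'
    'io.R'
    'experiment.R'
    'gillespie.R'
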