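Package: synprune
Title: Constraint-Based Pruning of Potential Synapses into Microcircuit Connectomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Converts axo-dendritic appositions ("potential synapses") between
    neurons of a layered cortical microcircuit into a biologically constrained
    synaptic connectome. Implements touch detection between neurite polylines
    with class-specific touch distances, compartment-exception filtering,
    closed-form derivation of three per-pathway pruning parameters from target
    connectivity statistics (mean and standard deviation of synapses per
    connection, bouton density), a three-step stochastic pruning engine
    (general, multi-synapse, and plasticity-reserve pruning), and a validation
    suite covering connection probabilities, bouton statistics, volumetric
    synapse densities, in-silico multi-patch sampling, common-neighbour
    clustering, and wiring-capacity estimates. Includes deterministic-seeded
    synthetic circuit generators at two fidelity levels and bundled reference
    tables of published connectivity statistics for rat somatosensory cortex.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
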