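Package: DenseConnectome
Title: Dense Statistical Connectomes from Sparse Neuron Morphologies
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Assembles average dense 3D circuit models of a brain region from
    sparse anatomical data (soma density fields, labeled neuron morphology
    reconstructions, cell-type tables) within a standardized reference frame of
    columns, laminar zones and local vertical axes, and derives a statistical
    connectome by a quantitative form of Peters' rule: axons are voxelized into
    bouton densities, dendrites and somata into postsynaptic-target (PST)
    densities, and expected synapse counts between every neuron pair are
    obtained by normalizing axo-dendritic overlap with all PSTs present in each
    voxel. Provides pairwise connection probabilities under a Poisson synapse
    model, population-level convergence and divergence statistics, directed
    triplet-motif spectra with uniform-null comparison, and a synthetic-fixture
    generator with dense brute-force oracles for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports: methods, stats, utils, Matrix, pracma
Suggests: testthat (>= 3.0.0), igraph, jsonlite, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
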