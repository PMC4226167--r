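# DenseConnectome

Statistical connectomes from sparse neuron morphologies, via a quantitative
form of Peters' rule.

## The problem

Complete synaptic wiring diagrams of a brain region ("dense connectomes")
cannot be measured directly at subcellular resolution and millimeter scales:
paired recordings reach only nearby neuron pairs in slices, and
electron-microscopic reconstruction is limited to tiny volumes. What *can* be
measured sparsely are 3D soma density fields, representative reconstructions
of dendrite and axon morphologies per cell type, and subcellular statistics
(dendritic spine densities, membrane surface areas, axonal bouton densities).

`DenseConnectome` assembles these sparse measurements into an average dense
3D circuit model inside a standardized reference frame (cylindrical columns,
laminar zones, a field of local vertical axes, a 50 um voxel grid set by the
inter-animal variability of the geometry), and then *measures* connectivity
statistically within the model. The package is aimed at quantitative
neuroanatomists who have such data — the bundled synthetic-fixture generator
emulates all required inputs at toy scale, so every stage can be exercised
without any dataset.

## The model

Structural overlap is never read as a binary "touch = connection". Instead,
for presynaptic neuron *i* and postsynaptic neuron *j*:

- the axon of *i* is clipped with the faces of every voxel and converted to a
  bouton density `B_i(x)` (length times the cell-type- and layer-specific
  bouton density per um);
- the dendrites and soma of *j* become a density of postsynaptic target sites
  (PSTs), `PST_j(x, T(i)) = Σ_L l_{j,L}(x) λ(L) + Σ_L a_{j,L}(x) α(L)`,
  summing spine (per um length) and surface (per um²) targets over the
  subcellular labels L ∈ {soma, apical, basal};
- within a voxel every PST is equally likely to receive any bouton, so the
  target probability is `p_j(x) = PST_j(x) / PST_all(x)`, normalized by the
  PSTs of **all** neurons present in that voxel;
- the expected synapse count is `Ĩ_ij(x) = B_i(x) · p_j(x)`, its sum
  `I_ij = Σ_x Ĩ_ij(x)` is the total innervation, the synapse count follows
  `Poisson(I_ij)`, and the pair connection probability is
  `p_ij = 1 − exp(−I_ij)`.

Unknown surface-PST densities α are derived from a bouton/PST balance
condition fitted on depth profiles by nonnegative least squares. On top of
the innervation matrix the package computes population statistics
(convergence, divergence, `P_AB`, the averaged synapse-count distribution
`n_AB`) and directed triplet-motif spectra (64 edge configurations reduced to
16 isomorphism classes) with a uniform-connectivity null comparison.

## Worked example

```r
library(DenseConnectome)

# closed-form pairwise statistics at a total innervation of 0.66
round(connectionProbability(0.66), 2)      # 0.48
d <- synapseCountDistribution(0.66)
round(100 * d$p[1:4])                       # 52 34 11  2   (% for n = 0..3)

# a synthetic two-column circuit: assemble, innervate, summarize
fx  <- makeFixtureNetwork(fixtureConfig(seed = 7))
net <- fx$network                           # 186 neurons, 4 cell types
im  <- pairwiseInnervation(net, fx$bundle$meta)
im                                          # 186 pre x 170 post, 6846 nonzero pairs

A <- selectNeurons(net, cellType = "TC", column = "C1")  # thalamic axons
B <- selectNeurons(net, cellType = "SS", column = "C1")  # polar spiny type
s <- populationSummary(im, A, B)
s$P_AB                                      # 0.28
c(s$convergenceMean, s$convergenceSD)       # 0.28 0.45

# triplet motifs of the SS population vs a uniform null
ss <- selectNeurons(net, cellType = "SS")
sp <- populationSpectrum(subsetInnervation(im, "SS", "SS"), ss,
                         nTriplets = 50, nRepeats = 10, seed = 1)
head(uniformNullComparison(sp, s$P_AB))
```

The summary numbers mean: a thalamocortical axon is expected to connect to
28% of the column's SS neurons (the convergence), with large cell-to-cell
spread (SD 0.45) because the toy circuit is small; the motif comparison shows
which triplet patterns are enriched or depleted relative to a homogeneous
random network with the same mean connection probability (e.g. here the
three-connected feedforward-loop classes deviate most).

A thin command-line front end over the same functions is provided in
`inst/scripts/densecon.R` (subcommands `fixtures`, `assemble`, `innervate`,
`motifs`).

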