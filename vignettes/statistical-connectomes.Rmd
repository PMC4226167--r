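---
title: "Statistical connectomes from sparse morphologies: model and methods"
author: "DenseConnectome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical connectomes from sparse morphologies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(DenseConnectome)
```

## Overview

`DenseConnectome` turns sparse anatomical measurements — soma density
fields, representative labeled reconstructions per cell type, spine/bouton
densities and membrane surface statistics — into an average dense 3D circuit
model and measures synaptic connectivity *within* the model. The key
methodological stance is a quantitative reading of Peters' rule: structural
axo-dendritic overlap is converted into an innervation *probability* by
normalizing against **all** postsynaptic targets present in each overlap
voxel, never interpreted as binary contact.

This vignette documents the model and its assumptions, the conventions and
tunable parameters, the numerical choices, what the synthetic fixtures do
and do not emulate, and the known limitations.

## Reference frame

The frame consists of a cubic voxel grid, cylindrical columns and per-column
laminar zones.

- **Voxels** are half-open boxes `[o + i·s, o + (i+1)·s)`, so every in-bounds
  point belongs to exactly one voxel and volumes partition exactly. The
  spacing `s` (default 50 um) should equal the inter-animal variability of
  the reference geometry: it is the smallest scale at which overlap between
  morphologies from different animals is meaningful. Statements about
  sub-voxel proximity are deliberately outside the model.
- **Columns** are cylinders given by a center, a unit axis, a radius and the
  depth interval `[top_depth, bottom_depth]` at which the axis pierces the
  pia and the white matter. We declare the center to be the midpoint of that
  axis segment, so the depth of a point `p` relative to a column is
  `dot(p − center, axis) + (top + bottom)/2`. Depth increases from the pia
  (all coordinates in um, right-handed, z growing with depth).
- **Point labels.** A point belongs to the column whose *axis segment* is
  nearest (ties broken by smallest column id, for determinism); it is
  *inside* if its radial distance is within the radius and its depth within
  the pia–WM interval, otherwise it is septum. Laminar zones are half-open
  depth intervals of the nearest column; depths outside every zone map to
  the sentinel `"outside"`.
- **Local vertical axes.** Curved cortex makes "vertical" position
  dependent. Each voxel's axis is the inverse-distance-weighted mean of the
  `k` nearest column axes, renormalized (exact on a column's own axis). The
  interpolation kernel is not dictated by the underlying method description,
  so `k` is a constructor parameter; the default `k = 3` uses the natural
  local neighborhood of a hexagonally packed column map while staying
  defined for arbitrary layouts.
- The curved pia/WM surfaces of a full anatomical pipeline are abstracted to
  per-column depth intervals (a height-field view). This preserves every
  quantity the innervation equations consume — laminar zone and depth — and
  matches what synthetic fixtures can provide.

## Morphologies

Reconstructions are rooted labeled trees with node radii; labels are
`soma`, `apical`, `basal`, `axon`, read from SWC v1 (structure codes
1/4/3/2 respectively; other codes rejected with the offending line). Branch
length sums parent–child segments whose child carries the label. Surface
area uses the lateral frustum rule per segment,
`π (r_parent + r_child) · length`, which is trapezoidal integration of the
diameter along the branch. Two declared conventions where the source
material is silent:

- a morphology whose soma is a single point contributes a sphere area
  `4πr²` to the voxel containing it; with two or more soma nodes the
  frustum rule applies to soma-labeled segments;
- the soma position is the unweighted centroid of soma nodes (deterministic
  and translation-equivariant).

Rigid transforms rotate about the soma and then translate
(`p → R(p − soma) + soma + t`); validity requires orthonormal `R` with
determinant 1 (tolerance 1e−9). Length and surface area are invariant by
construction, which the tests verify.

## Network assembly

1. **Soma placement.** Per voxel, the expected count is
   `density · 10³ · voxel volume (mm³)`; it is rounded *half-up* to an
   integer (the rounding direction is unspecified upstream; half-up is
   declared and tested) and positions are drawn uniformly inside the voxel.
   Total counts are therefore deterministic given the density field — a
   conservation law the acceptance tests check exactly.
2. **Labels.** Every soma gets its nearest column, inside/septum status,
   and a cell type drawn from the regional frequency table. Frequencies are
   conditional on the excitatory/inhibitory class because the two classes
   come from separate density fields; occupancy flags (column/septum/both)
   restrict eligibility and are validated.
3. **Dendrites.** A candidate reconstruction must match the cell type, be
   registered to the same column, and have its original soma within one
   voxel spacing of the new soma's depth along the column axis (so
   depth-specific morphology is preserved at frame resolution). One
   candidate is chosen uniformly; the transform translates the soma to the
   new position and rotates about the *local vertical axis* — vertical
   orientation is always preserved. For ordinary types the azimuth is
   uniform in [0, 2π) (maximal entropy given the constraint); for polar
   types (e.g. spiny stellates with dendrites pointing at the column
   center) the azimuth is chosen to map the reconstruction's
   soma-to-column-center bearing onto the new soma's bearing. If either
   bearing is degenerate (soma on the axis) the rotation defaults to zero.
4. **Axons** are selected by cell type and column only and are *not*
   transformed: translating or rotating an axon would destroy
   location-specific projection patterns (e.g. column-confined arbors).
   Only two criteria apply to axons, deliberately; no depth criterion.
5. **Long-range axons** (cell types without local somata, e.g.
   thalamocortical) are up-scaled by duplication until the per-column count
   from the cell-type table is reached. Duplication is round-robin over a
   seed-determined random order, so per-reconstruction multiplicities
   differ by at most one; an independent-uniform scheme would only add
   variance without information.
6. **Reproducibility.** A single run seed fans out to per-stage,
   per-neuron child seeds, so results are independent of iteration order
   and identical across repeated runs.

## Density fields and PSTs

Axons and dendrites are voxelized by exact clipping: each segment is split
at its crossings with the grid planes and each sub-segment's length and
frustum area accrue to the voxel containing its midpoint. Splitting is
parametric (no resampling), so per-label totals are conserved to float
precision; a dense resampling variant exists only as a test oracle.
Geometry outside the grid is dropped with a warning and recorded.

Bouton fields multiply clipped axon length by the cell type's per-zone
bouton density; the zone of a voxel is looked up at its center (a voxel is
atomic at frame resolution). Voxels outside all zones use density zero; a
named zone without a configured density is an error.

PST fields combine spine-type targets (length × λ per um) and surface-type
targets (area × α per um²) per subcellular label, with densities from the
meta-connectivity table keyed by (pre type, post type, label). An absent
key means "this pre type cannot synapse onto that structure" and
contributes zero. In the table, `alpha = NA` marks a density to be fitted;
a structurally impossible surface term is an explicit 0.

**Fitting α.** Unknown surface densities are derived from the balance
assumption that per depth layer the total bouton count equals the total
PST count. The 3D fields are collapsed to the grid's depth axis and α
solved by nonnegative least squares (`pracma::lsqnonneg`; densities are
physical counts per area, hence the sign constraint). A single 1D profile
cannot identify a full (pre type × post type × label) tensor, so unknowns
are tied — by default over (pre excitatory class, post type, label), with
`tying = "full"` available. Exactly collinear designs (e.g. two groups
multiplying the same area profile) are refused with the group names rather
than silently split. On a noise-free balanced profile the fit recovers the
generating α exactly; the tests assert recovery within 1%.

## Innervation, pairs and populations

Within a voxel all PSTs are equally likely targets, so
`p_j = PST_j / PST_all` (0 where no targets exist), `Ĩ_ij = B_i · p_j`,
`I_ij = Σ Ĩ_ij`, synapse counts are `Poisson(I_ij)` and
`p_ij = 1 − exp(−I_ij)`. The Poisson law is the limit of the per-voxel
binomial for many boutons and small target probabilities; an exact binomial
is kept in the tests to bound the total-variation error of the
approximation. Two invariants are tested exactly: `Σ_j p_j(x) = 1` wherever
`PST_all(x) > 0`, and `Σ_j Ĩ_ij(x) = B_i(x)` on those voxels (boutons are
distributed exhaustively over available targets). The per-voxel product
form `1 − Π_x P(n=0; Ĩ)` and the summed form `1 − exp(−I_ij)` agree to
1e−12.

`PST_all` always includes *all* dendrite-bearing neurons of the network,
not just the queried selection, and includes the postsynaptic neuron's own
contribution. Autapse entries (i = j) are computed but excluded from
population averages by default (flag-reversible); the method description is
silent on autapses, and paired-recording data they would be compared with
cannot observe them. No floor is applied to `PST_all` in sparsely populated
edge voxels: a lone target in a voxel legitimately has `p_j = 1`.

Population statistics are ensemble means of `p_ab`: convergence (over the
presynaptic population, per post neuron), divergence (mirror), and `P_AB`
(grand mean); the double-average identity links them and is tested on
random matrices. The averaged synapse-count distribution `n_AB` is the mean
of the per-pair Poisson mass functions; its mean equals the mean
innervation by linearity. The reported "synapse range" is `[1, q]` where
`q` is the smallest count whose cumulative probability, conditioned on at
least one synapse, reaches 99% — a declared operationalization of a
cumulative-range convention.

The convergence SD reported per population is across postsynaptic neurons
(not across bootstrap draws), which is the spread a paired-recording
experiment would sample.

## Triplet motifs

Three neurons have six ordered edges, fixed order
(1,2),(2,1),(1,3),(3,1),(2,3),(3,2); the 64 on/off configurations reduce
under the six node permutations to 16 classes — 7 three-connected, 6
two-connected, 2 one-connected, 1 empty. Isomorphism is decided by
exhaustive S₃ orbit enumeration (six permutations; exact, no graph library
in the production path — an igraph-based oracle cross-checks it in the
tests). Classes are numbered by edge count descending, ties by smallest
member configuration, so the empty motif is class 16; any figure-panel
ordering elsewhere is graphical and not guaranteed to coincide.

A triplet's spectrum multiplies, per configuration, edge probabilities
`p_e` or complements `1 − p_e`, and sums members per class; it always sums
to 1. Population spectra repeat (default) 10 times: 2000 triplets drawn
uniformly subject to any two triplets sharing at most one neuron
(equivalently: no neuron *pair* is reused), implemented by rejection
sampling with an attempt cap and a feasibility bound (`C(n,2)/3`), since
the sampling algorithm is not otherwise specified. The uniform null sets
all six probabilities to the population mean; deviations are
`(obs − null)/null` and z-scores divide by the across-repeat SD of the
observed spectrum (the null is deterministic, so it contributes no
variance).

## Synthetic fixtures and what they show

The generator emulates all seven input kinds at toy scale: a two-column
slab (50 um voxels, 10×6×9 grid, columns of radius 75 um, three laminar
zones over a 450 um depth), three local cell types (an ordinary excitatory
type, a polar column-confined type, an inhibitory type) plus a long-range
thalamocortical axon-only type up-scaled to 8 instances per column from a
library of 3; soma densities of 8·10³ mm⁻³ give exactly one soma per
occupied voxel so conservation checks are exact. Morphologies are
parametric random trees (persistent random walk with branching, exponential
radius taper, wall reflection) — they exercise labels, radii, registration
depth and geometry handling, **not** biological realism. Passing tests
therefore demonstrate correctness of the computational contracts
(conservation, normalization, equivariance, oracle equivalence,
determinism), not anatomical accuracy on real tissue; realistic densities,
layer thicknesses and arbor statistics are explicitly out of scope.

A deliberately tiny single-column bundle (≤ 10 neurons) backs the oracle
checks: a dense brute-force path — per-voxel Liang–Barsky slab clipping
into full arrays, dense normalization and sums, igraph isomorphism — shares
no computation code with the sparse production path and must agree to
1e−9. The problem sizes used throughout (186-neuron fixture, ≤10-neuron
oracle network, 100 random morphologies for conservation, 6 assembly seeds
× library sizes {1, 5} for the sample-size trend) were chosen so the full
suite exercises every pipeline stage in about a minute and a half on one
core while keeping every stochastic check comfortably inside its
statistical bounds.

## Numerical choices

- Half-open intervals everywhere (voxels, zones, depth windows): partitions
  without double counting; boundary points go to the +side / deeper zone.
- Soma-count rounding is half-up; banker's rounding would make counts
  depend on parity at exact .5 expectations.
- Segment split points are deduplicated at 1e−12 relative; zero-length
  sub-segments contribute zero and are harmless.
- `connectionProbability` uses `expm1` for accuracy at small innervation.
- The Poisson tabulation extends to the 1 − 1e−9 quantile by default.
- Degenerate cases error loudly: out-of-bounds queries, near-zero
  interpolated axes, PST_j exceeding PST_all, empty selections, infeasible
  triplet requests (with the feasible maximum), rank-deficient α designs.

## Limitations

- Laminar geometry is a height field per column; strongly curved regions
  where a voxel's zone varies within the voxel are approximated by the
  center lookup.
- The α balance fit identifies only as many tied groups as the depth
  profiles distinguish; the default tying is a modeling choice, not a
  measurement.
- Sub-voxel synapse placement, inhibitory subtype taxonomy, and
  realized-graph (sampled-network) motif counting are out of scope; motif
  spectra are probabilities, not counts in a sampled graph.
- Innervation values in the toy fixtures are much larger than in realistic
  tissue because only a handful of neurons compete per voxel; the
  normalization identities hold regardless of scale.
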