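---
title: "Neural morphometry for gray-matter dMRI modelling: methods and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Neural morphometry for gray-matter dMRI modelling: methods and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morphdmri)
```

## The problem

Diffusion-weighted MRI probes gray-matter microstructure indirectly: a
biophysical model maps cellular geometry to signal, and the inversion of
that model is only as good as its geometric assumptions. This package
computes, from 3-D reconstructions of neurons and glia, the morphological
quantities those models depend on, and converts them into time-scale
thresholds that say when a given geometric feature can influence a dMRI
measurement at all.

Everything operates on the SWC exchange format: a rooted tree of nodes,
each with a position (µm), a radius (µm — radius, not diameter) and a type
code. The first/root node is taken as the soma centre and its radius as the
nominal soma radius. Axons (type 2) are removed before analysis because
public reconstructions rarely contain complete axons; dendritic spines are
removed because they bias branch length and order.

## Preprocessing conventions

* **SWC dialect.** Comments (`#`) and blank lines are ignored; spaces and
  tabs both separate columns; columns past the seventh are ignored with a
  warning. Coordinates are treated as µm in an arbitrary frame; no axis
  reorientation is applied. On writing, ids are renumbered 1..N in
  parent-before-child order and numbers carry 9 significant digits, so a
  read/write round trip is lossless well past 6 significant digits.
* **Spine removal heuristic.** The field has no standard criterion, so we
  declare one: a terminal side branch is a spine when its total path length
  is at most 3 µm *and* its mean radius at most 0.3 µm *and* it attaches to
  a node that continues (a non-terminal attachment). The joint predicate is
  what protects short genuine dendritic tips — either threshold alone would
  remove them. Both thresholds are arguments; nodes carrying an explicit
  spine type code are always removed.
* **Quality control.** `validate_cell()` mirrors the inclusion criteria
  used for curated reconstruction sets: a connected acyclic tree, positive
  radii, genuine 3-D extent (non-zero variance on all three axes), and a
  flag when all dendritic radii are identical — the signature of a nominal
  fixed diameter rather than a measured one.

## Structural descriptors

The soma is the set of nodes within the nominal soma radius of the root
(connected to the root through such nodes). Edges leaving the soma are
split exactly at the soma sphere, so each primary projection starts on the
soma surface; the number of crossings is N_proj. One convention worth
stating: the radius assigned to the crossing point comes from the first
node outside the soma, never from the root — the root's radius describes
the soma, not the neurite.

Projections decompose into branches delimited by bifurcation and
termination nodes. A node with more than two daughters is treated as
stacked bifurcations and warned about. Branches are chains of cylindrical
sub-segments: each edge contributes a cylinder at the mean of its endpoint
radii (lateral surface only, no end caps). A frustum mode is available but
the plain-cylinder convention is the default and is what all reported
values use.

Per branch we compute: length (sum of sub-segment lengths), the
straightness ratio tau = chord/path (conventional tortuosity is 1/tau),
beading as the population coefficient of variation of sub-segment radii,
S/V as total lateral surface over total volume, undulation as the mean
angle between sub-segment directions and the branch chord, and the mean
curvature radius over interior node triplets (circumscribed-circle radius;
triplets with circumradius above 10^4 µm are treated as collinear and
excluded — without the cap, near-straight stretches would dominate the
mean with near-infinite radii). Bifurcation angles use the chord over the
first 5 µm of each daughter, which is robust to node jitter; note this
makes theta exactly scale-invariant only for daughters that are straight
over that chord.

Effective MR radii use the moment ratios (⟨R⁷⟩/⟨R³⟩)^(1/4) for soma
populations and (⟨R⁶⟩/⟨R²⟩)^(1/4) for branch populations — the exponent
pair differs because the dMRI signal weights spheres and cylinders by
different powers of the radius. Exponents are exposed as arguments. For a
single cell the soma "population" is a single radius and R_MRsoma equals
R_soma; the population-level quantity is meaningful across many cells.

Soma surface and volume default to the nominal soma sphere (`soma_method =
"sphere"`); a mesh-based mode iso-surfaces the soma node set instead. Any
soma surface definition at this scale carries a bias that can reach tens of
percent — mesh resolution is exposed for exactly that reason, and the
sphere default is the convention all tests pin down.

## Shape descriptors

Branch paths are cut into chunks of roughly 10 µm (the `target_length`
argument); chunks shorter than 2 µm are merged into a neighbour. Each chunk
yields one axial orientation — the principal axis of its nodes (chord for
2-node chunks) — weighted by its cylinder volume. Orientations are axes
(u and −u identified). The eigenvalues of the weighted scatter matrix,
trace-normalized and sorted ascending, give FA via the standard normalized
dispersion formula; FA is scale-free, so the trace normalization is purely
a reporting convention.

Because optical reconstructions are often compressed along the microscope's
Z axis (limited depth of field), the smallest eigenvalue can be
artificially depressed, inflating FA. The adjusted FA replaces tau1 by tau2
(no renormalization — FA is scale-free). This compensation presumes the
*uncompressed* cell is roughly axially symmetric (tau1 close to tau2); for
cells that are genuinely planar or strongly anisotropic at baseline it can
overcorrect.

Orientation dispersion: a Bingham density exp(−κ₁(u·e₁)² − κ₂(u·e₂)²) is
fitted about the two minor scatter axes by maximum likelihood, with the
normalizing constant evaluated by 64-point Gauss–Legendre quadrature on the
sphere (adequate to ~1e−8 for the concentrations encountered; no
special-function dependence). If κ₁/κ₂ ≥ 10 the sample is treated as planar
and κ₂ is the Watson concentration; otherwise the average of κ₁ and κ₂ is
used. The ratio 10 is a declared convention (`planarity_ratio`), chosen to
be far above the κ₁/κ₂ fluctuation of axially symmetric samples (below 1.5
at n = 1000 in our tests) and far below the ratio produced by a factor-0.3
Z compression. The Watson MLE itself solves E[(u·µ)²] = observed mean
squared projection by bisection to 1e−6, capped at κ = 10⁴ (perfectly
parallel samples report the cap). OD = (2/π)·arctan(1/κ).

## Topological descriptors

The persistence barcode uses path length from the soma attachment as the
filtration: each terminal is valued by its path length; at each bifurcation
the sibling with the smaller subtree maximum is eliminated, recording a bar
(path length of the bifurcation, eliminated subtree maximum); the longest
path survives to the root, giving the bar (0, max). Ties are broken by
branch id for reproducibility. Path length (not radial distance) is the
default filtration because it is intrinsic to the tree — rigid motions
leave barcodes unchanged, and uniform scaling scales them linearly; a
radial mode would entangle topology with embedding.

Persistence images are isotropic Gaussian KDEs of the bar points on a
100×100 grid, normalized to unit sum. Grid extent and bandwidth are not
standardized anywhere, so we declare them: for group comparisons the common
grid is [0, max death over both groups]² and the bandwidth is Scott's rule
on the pooled bar coordinates. A group image is the renormalized mean of
per-cell normalized images (per-cell first, so large cells do not dominate
by bar count; pooled-bar imaging is available as an alternative). The
topological distance is the L1 distance of pixel arrays, in [0, 2] since
each image sums to one.

Significance uses bootstrap resampling: cells are resampled with
replacement from the pooled set into two pseudo-groups of the original
sizes, the group distance is recomputed (per-cell images are cached, so
each iteration only averages matrices), and the p-value is the smoothed
fraction (1 + #{null ≥ observed}) / (n_boot + 1), with n_boot = 1000 by
default.

## Exchange times and relevance verdicts

Units are fixed package-wide: S/V in µm⁻¹, permeability κ in µm/s,
diffusivity D in µm²/ms, all times in ms. The residence time is
τᵢ = 1/((S/V)·κ) and the exchange time τ_ex = τᵢ·f_ec with extracellular
volume fraction f_ec = 0.30 by default.

The relevance calculators implement the standard order-of-magnitude
inequalities: restriction by a compartment of radius R is measurable when
5·D·t_d ≥ R²; curvedness when both 2DΔ and 2Dδ reach ⟨R_c⟩²; inter-branch
exchange is negligible for t_d ≪ L²/(2D). The soma–projection exchange time
approximates the soma as a sphere drained through N_proj circular openings
of branch radius, τ_soma = πR³/(3·R_branch·√N_proj·D); with a soma:projection
volume ratio of about 1:4 the branch residence time is 3·τ_soma and the
combined threshold is algebraically 0.75·τ_soma. Verdicts compare the
acquisition context (defaults: t_d = 60 ms, δ = 30 ms, Δ = 70 ms; D = 2 for
water, 0.4 for metabolites) against each inequality, boundary counting as
measurable. Undulation and orientation dispersion have no closed-form time
threshold; they are reported as measurable whenever present.

The spine correction models each spine as a spherical head on a cylindrical
neck and adds its per-µm surface and volume to the host cylinder's. The
default geometry — head radius 0.30 µm, neck radius 0.10 µm, neck length
0.8 µm — is this package's calibration: on a 0.6 µm branch it yields a
+27.7% S/V change at 1 spine/µm and +50.0% at 2 spines/µm, inside the
20–30% (and ≈50%) bands expected for rodent neurons, with corresponding
residence-time reductions of ~22% and ~33%. The geometry is tunable; the
relative change is permeability-independent.

## The synthetic-cell generator

The generator is the package's ground-truth oracle: it emits SWC cells
whose true feature values are known by construction, so every pipeline
stage can be tested offline without any external dataset.

A cell is a spherical soma (default radius 5 µm) with `n_projections`
(default 7) primary projections whose directions are drawn from a Watson
distribution of known κ (isotropic by default). Each projection is a binary
tree of `branching_depth` bifurcation levels (so maximum branch order is
depth + 1); branch lengths are lognormal (median 54 µm, sigma 0.4 — the
right-skew typical of real branch-length distributions), radii start at
0.6 µm with optional linear taper and sinusoidal beading, and the
centreline undulates as a planar sinusoid rotated randomly about the
chord. Spines, when requested, are explicit side branches (neck node +
head node) so that spine removal has a real target; an axon flag adds one
type-2 projection. Z compression scales z-coordinates only. The defaults
mirror the representative values for real neural cells (soma 5 µm, branch
radius 0.6 µm, branch length median 54 µm, 7 projections); the default
branching depth is 2, which keeps test cells at a few thousand nodes while
staying well inside the observed branch-order range (1–17).

Determinism is contractual: one RNG stream per cell, consumed in a
documented order (per projection: orientation; per branch, depth-first:
length, undulation azimuth, beading phase, daughter azimuth; spines last),
seeded per cell from the population master seed. Identical (spec, seed)
pairs produce byte-identical SWC output.

What the generator does **not** emulate: real soma are not spheres (their
surface is irregular, so soma S/V on real cells carries a bias the sphere
model does not show); real branch radii vary non-sinusoidally; real trees
are not balanced binary; spines have diverse morphologies; reconstructions
carry tracing noise and truncation artifacts. Passing the recovery tests
therefore demonstrates the correctness of the descriptor implementations,
not the realism of any biological claim.

Recovery tolerances (validated in the test suite at fixed seeds): lengths
1%, radii 2%, tau 1%, bifurcation angles 0.05 rad, Watson κ within 20% at
500 axes. The angle tolerance is met with gentle undulation (the 5 µm
chord estimator sees the undulation, not the true tangent, when the
undulation wavelength is comparable to the chord).

## Meshing

Meshes are built from the implicit union of one sphere per node and one
round cone (sphere-capped, linearly tapered capsule) per edge, iso-surfaced
at distance zero by marching tetrahedra on a regular grid — six tetrahedra
per cube around the main diagonal, a conforming decomposition, which makes
watertightness structural rather than empirical. The implicit-union route
(rather than boolean CSG) is what keeps branch junctions robust. The
default voxel is min(radius)/4 and a voxel larger than the smallest radius
is refused. On a 5 µm sphere at 0.4 µm voxels the volume error is ~0.3%;
convergence in voxel size is at least first order. Volumes use the
divergence theorem on outward-oriented faces; orientation is checked
per-triangle against the local inside direction and globally by the sign
of the total volume. Export formats: ASCII and binary little-endian PLY,
OBJ (1-based indices), ASCII STL with facet normals.

## Reporting

Population summaries report Q1/median/Q3 using linear-interpolation
quantiles (R type 7) — the method must be stated because quartile tables
are not comparable across quantile definitions. Spearman correlations use
average ranks for ties; the Bonferroni family is all off-diagonal feature
pairs within the record set being analyzed (per cell type when applied per
cell type).

## Problem sizes used in validation

The automated suite runs entirely on generated data: recovery tests use
populations of 5 cells at branching depth 2 (~50 branches per cell);
Watson/Bingham fits use 500–1000 axes; the bootstrap null calibration uses
20 independent two-group draws (12 small cells per draw) at 199 bootstrap
iterations each; meshing oracles use a 5 µm sphere at 0.4 µm voxels and a
50 µm cylinder at 0.15 µm voxels. These sizes were chosen to exercise every
code path with comfortable statistical margins.

## Known limitations

* The soma-sphere default under-represents irregular soma surfaces; the
  mesh mode reduces but does not remove that bias.
* Reported population values from real repositories depend on inclusion
  criteria and reconstruction quality; this package reproduces the
  *methods*, not any specific published population table.
* The adjusted FA overcorrects for cells that are genuinely planar before
  compression.
* The spine correction is a surface/volume bookkeeping model; it does not
  model the spine neck as a diffusion barrier.
* Exchange calculators assume purely passive membranes (no active
  transport, no water channels).
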