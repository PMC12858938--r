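# morphdmri

Brain-cell morphometry for diffusion-MRI microstructure modelling.

Biophysical models of the diffusion-weighted MRI (dMRI) signal in gray
matter need to know which cellular-scale features — soma size, neurite
caliber, branching, orientation dispersion, membrane exchange — actually
influence the measurement. `morphdmri` computes those features from 3-D
neural reconstructions (neurons and glia) in the standard SWC format, and
turns them into concrete dMRI-relevance verdicts. It is aimed at the
microstructure-imaging community: people building or validating models such
as NODDI, SANDI or NEXI, and people generating numerical substrates for
Monte Carlo diffusion simulators.

## What it computes

**Structural descriptors** (per cell and per branch). The cell is split at
the nominal soma radius (the root node's radius); everything outside is
decomposed into branches delimited by bifurcation and termination nodes,
modelled as chains of cylindrical sub-segments. From these the package
computes: domain radius R_domain, number of primary projections N_proj,
branch order BO, soma radius R_soma and surface-to-volume ratio S/V_soma,
the projection-coverage fraction eta_soma, branch length L_branch, mean
branch radius R_branch, beading CV_branch = sd(r)/mean(r), branch S/V,
undulation µOD_branch (mean angle between sub-segments and the branch
chord), mean curvature radius R_c, straightness ratio tau_branch
(chord/path, inverse of conventional tortuosity), and bifurcation angle
theta_branch. Moment-weighted effective MR radii follow

    R_MRsoma  = (<R^7> / <R^3>)^(1/4)      R_MRbranch = (<R^6> / <R^2>)^(1/4)

**Shape descriptors.** Branches are cut into ~10 µm segments; the
volume-weighted orientation scatter matrix T = Σ wᵢ uᵢuᵢᵀ / Σ wᵢ yields
eigenvalues τ₁ ≤ τ₂ ≤ τ₃ (trace-normalized) and

    FA = sqrt( 3/2 · Σ(τᵢ − τ̄)² / Στᵢ² )

plus an adjusted FA (τ₁ := τ₂) that compensates the depth-of-field
compression artifact of optical reconstructions. Orientation dispersion
comes from a Watson/Bingham fit: OD = (2/π)·arctan(1/κ), with κ taken from
the Bingham concentrations (κ₂ if κ₁ ≫ κ₂, else their mean).

**Topology.** The Topological Morphology Descriptor: path-length
persistence barcodes per projection (one bar per terminal; at each
bifurcation the shorter sibling dies), KDE persistence images normalized to
unit sum, L1 topological distances D ∈ [0, 2], and bootstrap significance
of group differences.

**Exchange and dMRI relevance.** Residence time τᵢ = 1/((S/V)·κ_perm),
exchange time τ_ex = τᵢ·f_ec, restriction thresholds R²/(5D), curvature
thresholds R_c²/(2D), branching threshold L²/(2D), the soma–projection
exchange threshold 0.75·πR³/(3·R_branch·√N_proj·D), and a spine
surface-to-volume correction. `relevance_report()` evaluates all of these
against water (D = 2 µm²/ms) and metabolite (D = 0.4 µm²/ms) acquisition
contexts.

**Meshing.** Watertight triangulated surfaces (union of node spheres and
tapered capsules, marching tetrahedra) exported to PLY/OBJ/STL for Monte
Carlo simulators.

**Synthetic cells.** A generator with fully known ground truth (soma
radius, branch lengths/radii/tortuosity, Watson-distributed orientations,
beading, undulation, spines, Z-compression) used to validate every stage.

## Worked example

```r
library(morphdmri)

spec <- synthetic_cell_spec(branching_depth = 2, undulation_amplitude = 1.5,
                            beading_amplitude = 0.06)
g   <- generate_cell(spec, seed = 7)
rec <- analyze_cell(g$cell)   # strip axons/spines, structural + shape record
round(rec[, c("R_domain", "N_proj", "BO", "R_soma", "SV_branch", "L_branch",
              "R_branch", "tau_branch", "FA", "adjFA", "kappa", "OD")], 3)
#>   R_domain N_proj BO R_soma SV_branch L_branch R_branch tau_branch    FA adjFA kappa    OD
#> 1  260.324      7  3      5      3.32   62.954      0.6       0.95 0.573 0.321 2.787 0.219
```

The cell spans 260 µm, has 7 primary projections with branch order 3,
branches of ~63 µm at radius 0.6 µm (S/V = 3.3 µm⁻¹, near the 2/r cylinder
value), nearly straight paths (τ = 0.95), moderate anisotropy (FA 0.57) and
an orientation dispersion of 0.22. Feeding the record to the threshold
calculators:

```r
dplyr::filter(relevance_report(rec), context == "water")
#>                  mechanism context threshold_ms compared_to    verdict
#> 1         soma restriction   water          2.5         t_d measurable
#> 2 soma-projection exchange   water         30.9         t_d measurable
#> 3       domain restriction   water       6776.8         t_d negligible
#> 4               curvedness   water        450.0 delta,Delta negligible
#> 5               undulation   water           NA             measurable
#> 6                branching   water        990.8         t_d negligible
#> 7      permeative exchange   water          4.5         t_d measurable
#> 8   orientation dispersion   water           NA             measurable
```

At a typical in vivo acquisition (t_d = 60 ms), soma restriction,
soma–projection exchange, permeative exchange and orientation dispersion
are measurable for this cell; whole-domain restriction, branch curvedness
and branching are not.

Real reconstructions are analyzed the same way: `read_swc("cell.swc") |>
analyze_cell()`, or `batch_analyze("swc_dir/")` for a directory. A thin
command-line wrapper is installed at `inst/cli/morphdmri` (subcommands
`analyze`, `batch`, `tmd`, `mesh`, `simulate`, `report`).

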