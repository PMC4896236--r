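---
title: "Interface descriptors for classifying phosphorylation patterns"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interface descriptors for classifying phosphorylation patterns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ptmscope)
```

## The problem and the model

Multimeric proteins regulated by interface phosphorylation — small
heat-shock proteins are the canonical case — change their assembly
state when a few serines at a subunit interface acquire a phosphate.
Whether a given combination of phosphosites loosens or tightens the
interface is, in principle, a question for long simulations of the
whole assembly; in practice those are out of reach for every one of the
$2^N$ modification patterns. `ptmscope` implements a desk-scale
surrogate: short conformational ensembles of the *interface subunit*
(a two-chain complex) are reduced to nine physicochemical descriptors,
and the patterns are classified in descriptor space.

The descriptor vector for one system is
$$
d = (\mathrm{SAS}_{tot},\ \mathrm{SAS}_{phob},\ \mathrm{SAS}_{buried},\
\mathrm{HB},\ \mathrm{GapIndex},\ V_{gap},\ |E_{LJ}|,\
\mathrm{AbsMin},\ \#\mathrm{Min}),
$$
five terms averaged over the equilibrated frames, two evaluated on a
single representative conformation, and two evaluated on the
free-energy landscape of the ensemble. A study of $N$ phosphosites
appends $N$ binary indicators (1 = phosphorylated), giving e.g. a
13-column feature matrix for a two-chain, two-serine dimer.

The physical intuition: a detaching interface *gains* exposed surface
(total and hydrophobic SAS), *loses* buried surface, inter-chain
hydrogen bonds and dispersion energy, and its inter-chain cleft (gap
volume, gap index) widens; a metastable structure spreads its landscape
occupancy over many shallow basins (low AbsMin, high #Min), a stable
one concentrates it (high AbsMin, few basins).

## Descriptor definitions and parameters

**Solvent-accessible surface (probe 1.4 Å, 960 points/atom).**
Shrake–Rupley sphere sampling on a deterministic Fibonacci lattice: the
accessible fraction of each atom's probe-expanded sphere scales its
analytic area, so an isolated atom is exact and results are
reproducible at any sampling density. Convergence is smooth in
`n_points`; 960 points put the two-sphere test case within 1% of the
closed-form union area. The hydrophobic subset is C/S atoms of
ALA, VAL, LEU, ILE, MET, PHE, TRP, PRO, GLY (configurable — there is no
universal convention, so the set is an explicit argument). Buried
surface is $\mathrm{SAS}_A + \mathrm{SAS}_B - \mathrm{SAS}_{AB}$ with
each chain kept in its complex conformation.

**Hydrogen bonds (D–A ≤ 3.5 Å, H–D–A ≤ 30°).** Common MD-analysis
geometric criteria; donors are N/O atoms carrying a hydrogen, and only
donor–acceptor pairs on *different* chains count. Structures without
hydrogens (crystal structures) fall back to a heavy-atom distance
criterion, counting each unordered cross-chain N/O pair once. The
reported value is the mean count per equilibrated frame, hence
real-valued.

**Lennard-Jones energy (per-element 12-6 table, 10 Å cutoff).**
$\left|\sum 4\varepsilon_{ij}[(\sigma_{ij}/r)^{12}-(\sigma_{ij}/r)^6]\right|$
over inter-chain pairs, Lorentz–Berthelot combination. The bundled
per-element parameters are deliberately coarse: only *relative*
differences between modification variants enter the statistics, not
force-field-accurate energies. The absolute value is reported so the
descriptor grows with interaction strength.

**Gap volume and gap index (0.8 Å grid, 5 Å pair cutoff, spheres
≥ 1 Å).** For every inter-chain atom pair with a positive
surface-to-surface separation up to the cutoff, a trial sphere sits at
the midpoint of the inter-surface segment with radius half the
separation, is shrunk to the clearance of its nearest atom, and is kept
if it retains a 1 Å radius. The union of kept spheres is rasterized and
its voxel volume is $V_{gap}$. Two numerical choices matter:

* *Shrink-only refinement.* The construction is specified only to the
  level of "fit a sphere that penetrates no atom"; shrinking against
  the nearest clashing atom (rather than also translating the centre)
  is deterministic and reproduces the construction at that level.
* *Pose-independent rasterization.* The voxel grid is aligned to the
  principal axes of the sphere centres and centred on their centroid,
  so the volume estimate is exactly invariant under rigid motion of the
  complex (a world-aligned grid changes the count by tens of voxels
  under rotation). The alignment is ill-defined only when the centre
  cloud has degenerate principal axes (an exactly square lattice);
  jittered or biological configurations are safely non-degenerate.

The gap index divides $V_{gap}$ by the interface ASA. "Interface ASA"
has no unique definition; the default is the per-side convention
$\mathrm{SAS}_{buried}/2$, with the full buried area available as
`asa_mode = "total"`. When the chains share no buried surface (or no
gap sphere survives) the gap index is defined as 0. Both static
parameters are evaluated on the representative conformation: the centre
of the largest GROMOS cluster (pairwise Cα RMSD after Kabsch
superposition, 0.3 nm neighbour cutoff, ties to the lowest frame index)
— a real sampled structure, not a coordinate average, which could be
stereochemically meaningless.

**Landscape statistics (20×20 grid, 3×3 boxes, 0.7 threshold).**
Essential dynamics: equilibrated Cα frames are superposed on their mean
(one fixed-point iteration), the $3n \times 3n$ positional covariance
is eigendecomposed, and frames are projected on the two leading modes.
Occupancy on a 20×20 equal-width histogram over the data range is the
landscape; all statistics operate on occupancy probabilities (high
occupancy = low free energy), so $-kT\ln p$ is computed only for
plotting and log(0) never arises. AbsMin is the largest 3×3 *sliding*
window sum; a window is a basin when its sum reaches 0.7 × AbsMin *and*
it is a local maximum among the windows overlapping it (non-maximum
suppression, ties to the lower row/column index). Sliding windows with
suppression were chosen over disjoint tiles because a tiling makes the
basin count depend on the grid phase relative to the basins; at least
one basin (the absolute minimum itself) is always reported. Eigenvector
signs follow a fixed convention (dominant component positive), and the
landscape statistics are invariant to axis reflection by construction
of the histogram.

**Equilibration detection (window 10% of frames, slope ≤ 1e-4
nm/frame).** The equilibrated portion of a trajectory is usually judged
from the RMSD plot by eye; the package uses a deterministic surrogate:
the window starts at the first frame from which every subsequent
sliding-window linear RMSD slope stays within tolerance through the
end. A trajectory that never flattens falls back to its last half, with
a warning. On noisy stationary series the strict default tolerance
often triggers the fallback — a conservative outcome (the last half of
a stationary series is a valid equilibrated window).

## The statistical layer

Validation-style studies compare a wild-type/modified pair per protein:
each descriptor's two values are divided by their pair mean, which
removes protein-specific scale exactly (each normalized pair sums to 2;
within-pair ratios are untouched; indicator columns are exempt). PCA
defaults to the correlation matrix (unit-variance scaling): the
descriptors span Å², kJ/mol, counts and probabilities, and without
scaling the ~10³-Å² surface terms would own every component. Loadings
are unit-norm eigenvector columns with a deterministic sign convention;
the sdev > 1 rule flags the components worth inspecting. Clustering
uses `stats::kmeans` (Hartigan–Wong) on the leading scores with 50
seeded restarts — deterministic for a fixed seed, with the variant
recorded in the result's metadata; an elbow/silhouette report is
provided instead of an automatic choice of k. Site–descriptor Pearson
correlations are flagged at |r| > 0.30; zero-variance columns yield
r = 0, unflagged, with a warning rather than NA propagation. Systems
lacking a descriptor are excluded with a warning, never imputed.
Higher-order assemblies built from the studied interface (e.g. a
hexamer of dimers) are scored as the element-wise mean of their
constituent interface descriptor vectors.

## What the synthetic generators emulate

* `make_toy_dimer`: two mirror-image poly-alanine-like chains (backbone
  N/H/CA/C/O) across a planar interface at a prescribed
  surface-to-surface separation, with 0.05 Å seeded jitter. It emulates
  *interface geometry* — burial, cleft, dispersion contact — and their
  monotone response to separation. It does not emulate side-chain
  chemistry or real backbone stereochemistry; notably, with separation
  defined as a strict vdW-surface distance, cross-chain donor–acceptor
  distances always exceed the 3.5 Å criterion, so the toy dimer forms
  no inter-chain hydrogen bonds — hydrogen-bond behaviour is tested on
  constructed donor–H–acceptor triplets instead.
* `make_harmonic_ensemble`: frames displaced along random orthonormal
  Cα modes orthogonal to the rigid-body subspace (so superposition
  cannot absorb them), with Gaussian amplitudes of planted variance.
  Ground truth for essential dynamics; default variances 4 and 1 Ų are
  of the magnitude of dominant backbone modes in nanosecond ensembles.
* `make_basin_ensemble`: latent 2-D Gaussian-mixture samples embedded
  along two fixed internal modes. Defaults (unit latent width, centres
  8 latent units apart, 600 frames) give well-separated, recoverable
  basins; a precondition warning fires below 6σ separation. Ground
  truth for the landscape pipeline.
* `make_feature_study`: descriptor matrices on realistic scales
  (e.g. 12000 Ų total SAS, 0.15 AbsMin) with 5% relative noise, a
  planted detached/compact contrast of chosen effect size, and a shared
  per-pair size factor that pairwise normalization must remove.

Every generator is a pure function of its seed and restores the
caller's RNG stream. Passing tests on these generators demonstrates
that the estimators recover *planted* structure under realistic noise;
they do not demonstrate force-field accuracy, convergence of real MD
sampling, or transferability of the bundled LJ/radius tables — on real
data those remain the user's responsibility.

## Problem sizes and test design

The test suite and the acceptance script run desk-scale studies chosen
to keep recovery claims statistically meaningful: 16-pattern studies
use 4-residue chains with 20-frame ensembles and 120-point SAS
sampling; essential-dynamics recovery uses 1000 frames (sampling error
of an eigenvalue ≈ √(2/n) ≈ 4.5%, against a 10% assertion); landscape
recovery uses 600 frames × 20 seeds per basin count, asserting ≥95%
recovery — at 600 frames the 20×20 histogram of a single basin is noisy
enough that a spurious second window occasionally clears the 0.7
threshold, which is an intrinsic property of the sliding-window rule,
not a failure of the estimator. The analytic slab oracle for the gap
volume uses a 24×28 rectangular plate: rectangular so the principal
axes are non-degenerate, large so the sphere union's edge fringe (a
finite-size artifact) stays small against the analytic volume; the
~10% residual excess is the intrinsic thickness bulge of filling a slab
with spheres.

## Known limitations

* Descriptors assume a two-chain interface; larger complexes must be
  decomposed into interface pairs (the multimer aggregation rule then
  combines them).
* The LJ and radius tables are per-element; no force-field typing.
* Binary trajectory formats (XTC/DCD) are not read; ensembles
  interchange as multi-model PDB.
* The gap-sphere volume, like any sphere-filling estimate, carries a
  systematic positive bias for thin clefts; comparisons across variants
  (its role here) are unaffected.
* Equilibration detection is a heuristic surrogate for visual
  inspection; inspect the attached RMSD series
  (`attr(t, "rmsd_nm")`) when in doubt.
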