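# ptmscope

Phosphorylation of serines at the interface of a multimeric protein can
loosen or lock the assembly — small heat-shock proteins such as
αB-Crystallin switch between oligomeric states this way. Simulating
every modification pattern of a large multimer long enough to watch the
transition is impractical, but short conformational ensembles of the
interface subunit already carry the signal. `ptmscope` extracts that
signal: it computes nine physicochemical descriptors of a two-chain
interface from a conformational ensemble, combines them with binary
phosphosite indicators, and classifies modification patterns by their
predicted effect on the interface (detaching vs. compacting).

It is aimed at structural bioinformaticians who have per-variant
ensembles (multi-model PDB; e.g. snapshots from nanosecond-scale MD)
and want a reproducible, desk-scale classification of PTM patterns.

## The descriptors

For each system the package computes, over the equilibrated window of
the ensemble:

| descriptor | definition |
|---|---|
| Total SAS | solvent-accessible surface area (Shrake–Rupley, probe 1.4 Å), trajectory mean |
| Hydrophobic SAS | SAS of C/S atoms of apolar residues, trajectory mean |
| Buried SAS | SAS(monomer 1) + SAS(monomer 2) − SAS(complex), trajectory mean |
| HB | inter-chain hydrogen bonds (D–A ≤ 3.5 Å, H–D–A ≤ 30°), mean count per frame |
| Gap_Index | gap volume / interface ASA (per-side ΔASA/2 convention), on the representative conformation |
| Volume | inter-chain gap volume by the gap-sphere construction (0.8 Å grid, 5 Å pair cutoff, spheres ≥ 1 Å) |
| E_LJ | absolute inter-chain Lennard-Jones 12-6 energy, trajectory mean |
| AbsMin | occupancy of the most populated 3×3 region of the 20×20 free-energy landscape over the first two essential-dynamics modes |
| #Min | number of landscape basins whose occupancy reaches 0.7 × AbsMin |

The representative conformation is the centre of the largest GROMOS
cluster (Cα RMSD, 0.3 nm cutoff) of the equilibrated frames. The
statistical layer normalizes wild-type/modified pairs by their mean,
runs correlation-matrix PCA (unit-norm loadings, sdev > 1 retention
rule), clusters systems by k-means (Hartigan–Wong, seeded restarts) on
the leading components, and reports Pearson correlations between each
phosphosite indicator and each descriptor, flagged at |r| > 0.30.

A synthetic module generates toy dimers with tunable interface
separation, harmonic ensembles with planted covariance, multi-basin
ensembles with a planted landscape, and feature matrices with a planted
detached/compact split, so every stage is testable against known ground
truth without MD input.

## Worked example

Nine descriptors for one toy variant from a 200-frame ensemble:

```r
library(ptmscope)
s <- make_toy_dimer(n_res = 6, separation = 2, seed = 1)
t <- make_harmonic_ensemble(s, mode_variances = c(4, 1),
                            n_frames = 200, seed = 1)
d <- compute_descriptors(t, descriptor_config(n_points = 240))
round(d, 3)
#>       total_sas hydrophobic_sas      buried_sas              hb       gap_index
#>        1108.105         574.738          68.274           0.000           4.460
#>          volume            e_lj         abs_min           n_min
#>         151.552           4.873           0.140           2.000
```

The complex exposes ~1108 Å² of surface, buries ~68 Å² at the
interface, and its inter-chain cleft (152 Å³ over ~34 Å² of interface
per side) gives a gap index of 4.5 Å; the landscape has two occupied
basins, the deeper one holding 14% of the frames. A detaching interface
raises total SAS, volume and gap index and lowers buried SAS, HB and
|E_LJ| — the contrast the classifier uses:

```r
m  <- make_feature_study(n_per_group = 8, effect_size = 5, seed = 1)
mn <- pairwise_normalize(m, attr(m, "pairs"))
pca <- run_pca(mn)
round(pca$cumulative_variance[1:3], 3)
#> [1] 0.960 0.977 0.985
cl <- kmeans_on_pcs(pca, n_pcs = 3, k = 2, seed = 1)
table(cluster = cl$labels, truth = attr(m, "group"))
#>        truth
#> cluster detached compact
#>       1        0       8
#>       2        8       0
```

Sixteen systems in two planted regimes are separated perfectly by
k-means on the first three components.

A command-line front end is installed at `exec/ptmscope`
(subcommands `load`, `descriptors`, `representative`, `gap`, `fel`,
`analyze`, `simulate`); every subcommand is deterministic for a fixed
`--seed`.

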