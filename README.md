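# piezotraj

Trajectory analysis for molecular-dynamics studies of Piezo1, the trimeric
mechanosensitive cation channel whose three curved arms force the
surrounding bilayer into an inverted dome. The package is aimed at
computational biophysicists who need the standard post-processing chain
for such simulations — and a way to verify every stage of it without
access to the original multi-microsecond trajectories.

It implements, as tested R functions behind a set of narrative analysis
scripts:

- **Membrane dome curvature** — per-leaflet lipid headgroup heights are
  tiled into periodic images, gridded (4.6 Å spacing, optional local-mean
  smoothing with kernel size ⌈√(nx·ny)/4⌉) and fitted per frame with a
  radial Gaussian
  `z(x,y) = z0 + zh·exp(−((x−rx)² + (y−ry)²)/σ²)`;
  the apex curvature radius follows from the peak second derivative
  `d = −2·zh/σ²` as `R = (1+d²)^{3/2}/d`.
- **Ligand-binding detection** — windowed RMSF of each simulated ligand
  (non-overlapping 24 ns windows), stability ranking, contact-residue
  reports at a 4 Å heavy-atom cutoff, and classification of the membrane
  leaflet through which a ligand enters.
- **Dynamical residue networks** — Pearson correlations of Cα motions on a
  4.5 Å/75 % contact mask, edge lengths −log|C|, Girvan–Newman community
  detection (deterministic tie-breaks, modularity scored on |C| weights),
  and inter-community contact summaries.
- **Arm motion PCA** — covariance eigenmodes of Cα coordinates over a
  stretch interval, per-mode projections, and per-arm tilt/twist angle
  series from the spherical angles of the arm axis.
- **Pore ion occupancy** — minimum-image counts of each ion species within
  5 Å of a region selection, sampled every 24 ns, with cation:anion
  selectivity summaries.
- **Functional assays** — ΔF/F₀ = (F_max − F₀)/F₀ after a stimulus,
  Boltzmann fits `I/Imax = 1/(1+exp((P50−P)/k))` of pressure–response
  data, and two-tailed Mann–Whitney U tests (exact by enumeration up to
  combined n = 12, tie-corrected normal approximation beyond).
- **Synthetic data with ground truth** — generators for curved bilayers on
  analytic domes (with flattening schedules), bound/free ligand ensembles,
  planted correlated-motion communities, scheduled arm tilts, biased ion
  boxes and parametric assay readouts. Every generator is
  seed-deterministic and emits its ground truth.

Trajectory I/O (PDB, multi-model PDB, DCD) goes through
[bio3d](https://cran.r-project.org/package=bio3d); graphs through igraph;
nonlinear fits through minpack.lm.

## Worked example

Generate a membrane in the regime of the Piezo1 simulations (dome depth
−30 Å, width 70 Å in a 190.1 × 190.1 Å² box, 1 Å height noise) and recover
its curvature radius:

```r
library(piezotraj)
dome <- make_dome_membrane(seed = 101, n_frames = 1, noise_sd = 1)
cfg  <- list(resname = "POPC", head_names = "P", tail_name = "T")
cs   <- curvature_timeseries(dome$traj, cfg, smooth = FALSE, span = NA)
cs[, c("leaflet", "R_nm", "residual_A")]
#>   leaflet     R_nm residual_A
#> 1   upper 7.865029  0.9954048
#> 2   lower 7.889861  0.9976754
abs(dome$truth$R_A) / 10   # analytic radius for these parameters
#> [1] 8.168503
```

The fitted 7.87/7.89 nm against the analytic 8.17 nm (≈ 4 % off at 1 Å
height noise on a single frame) lands in the ~8–10 nm regime expected for
the Piezo1 dome; averaging over frames tightens it further. The
numbered scripts under `analysis/` run each stage end to end and print
what they find:

```sh
Rscript analysis/01_membrane_curvature.R
#> frames analyzed: 40; initial |R|: 7.87 nm (analytic 8.17 nm)
#> median |R_fit - R_true|/R_true while dome persists: 3.31%
#> ...
Rscript analysis/02_ligand_binding.R
#> most stable ligand: L1 (mean tail RMSF 0.54 A); truth: L1,L2
#> its binding-site residues (contact fraction >= 0.5): 1718, 1719, 1720
#> scripted membrane entry classified: lower leaflet at frame 17 (19.2 ns)
```

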