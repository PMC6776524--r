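---
title: "Methods: trajectory analysis of Piezo1 membrane mechanics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trajectory analysis of Piezo1 membrane mechanics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

piezotraj implements the trajectory-analysis computations used to study the
mechanosensitive channel Piezo1 in molecular-dynamics simulations: the
curvature of the membrane dome the channel imposes on the bilayer, the
detection of spontaneously binding agonist molecules, the community
structure of correlated residue motion, the principal components of arm
motion under membrane tension, ion occupancy near the pore, and the
statistics of the accompanying functional assays. Because multi-microsecond
trajectories of a ~1M-atom system are not practical inputs for routine
verification, the package pairs every analysis with a synthetic-data
generator that produces inputs with known ground truth in the same
numerical regimes; every claim the package makes about itself is a
recovery statement against that ground truth.

## Trajectory handling

Topologies are read from PDB (via bio3d), coordinates from multi-model PDB
or DCD. XTC is not supported (no installed reader); DCD is written by a
minimal single-precision CHARMM-format writer so binary round-trips can be
exercised from generated data. Boxes are orthorhombic only — the simulated
system (190.1 x 190.1 x 177.5 A^3) is orthorhombic, and triclinic input is
refused explicitly rather than silently mishandled.

Re-imaging translates whole molecules by integer box multiples until their
center of mass lies within half a box length of an anchor selection,
reproducing the usual "autoimage" preprocessing; intra-molecule geometry is
untouched. Superposition is standard least-squares rigid-body fitting
(Kabsch/SVD) with a determinant check so reflections are never applied.
RMSD series are best-fit per frame on the same selection. The default
backbone is N/CA/C/O and the default frame interval is 1.2 ns (the
trajectory output spacing); both are configurable. Published RMSD traces do
not state whether the reference is the first frame or the starting model;
we default to frame 0 and expose the reference index.

## Membrane curvature

The pipeline follows the published protocol: per-lipid headgroup
centers of mass are split by leaflet, tiled into the eight adjacent x-y
periodic images, interpolated onto a grid of 4.6 A spacing (about twice
the molecular radius of a phosphate ion) covering all points with one
spacing of padding, optionally smoothed with a uniform "local mean" kernel
of size ceil(sqrt(nx*ny)/4) with wrap-mode edges, and fitted per frame with
the radial Gaussian

z(x, y) = z0 + zh * exp(-((x - rx)^2 + (y - ry)^2) / sigma^2),

from which the apex curvature radius follows in closed form from the peak
second derivative d = -2*zh/sigma^2 as R = (1 + d^2)^(3/2) / d. The
(1 + d^2)^(3/2) factor is implemented exactly as the protocol states it,
although it is dimensionally inconsistent if d is read strictly as a second
derivative; in the operating regime (|d| ~ 0.01/A) the difference from
1/|d| is below 0.03%, far inside every tolerance used here.

Two choices deserve explanation.

*Leaflet assignment.* A lipid is "upper" iff its head atom lies above its
tail atom. This is valid because the Piezo dome never folds past vertical
— in both the simulations and the generator the surface stays a graph over
the x-y plane.

*Gridding.* The reference protocol used Delaunay-based linear
interpolation of scattered points; no installed R package provides that
primitive, so the package gridder deposits each tiled point onto nearby
gridpoints with separable triangular weights (half-width two cells) and
divides by the accumulated weight. This weighted binning acts as a
low-pass kernel of known variance ((2h)^2/6 per axis at spacing h), which
would bias the fitted dome amplitude at the half-percent level; a
discrete-Laplacian sharpening step (z <- z - (w^2/12) lap z) cancels that
second-order bias exactly, leaving only fourth-order residuals. The
scheme is exact on constant fields, equivariant under constant height
offsets, and recovers analytic dome radii well within 0.5% worst-case at
the benchmark density of one lipid per (8 A)^2.

*Smoothing in recovery benchmarks.* The uniform kernel prescribed for
visualization attenuates a Gaussian of width sigma by the separable factor
[(sigma*sqrt(pi)/(k*h)) * erf(k*h/(2*sigma))]^2 at the peak (about 10% for
the 13-cell kernel at sigma = 70 A, worse for narrower domes). That bias
belongs to the display pipeline, not to the curvature estimator, so all
recovery benchmarks in tests and the acceptance script run on the
unsmoothed grid; smoothing remains the default in the user-facing time
series, and `analysis/01_membrane_curvature.R` prints the size of the
smoothing bias rather than hiding it. Fit failures at single frames yield
missing values so long series survive isolated bad frames.

Dome-fit initialization is deterministic and scale-aware: z0 at the grid
median, zh at extremum-minus-median, center at the grid extremum, sigma at
a quarter of the smaller grid extent, with sigma bounded in (1 A, grid
diagonal) and two fallback starts. The benchmark box is chosen as
max(190.1, 5*sigma) per side so the plateau is actually present in the
field of view; with narrower boxes the plateau parameter z0 and the depth
zh become degenerate and no estimator can separate them.

## Ligand mobility

Ligand RMSF is computed per non-overlapping window (default 20 frames =
24 ns at the 1.2 ns output interval, matching the accumulation cadence of
the published analysis) over all ligand heavy atoms: the root mean square
deviation from the window-mean atomic positions. Ranking uses the
time-averaged RMSF over a configurable tail interval (default the second
half), ascending, with ties broken by label order and flagged. Whether the
published mobility traces were atom-wise or center-of-mass based is not
stated; atom-wise is the default here because whole-ligand mobility is what
the windowed color maps display. Contacts use a 4.0 A heavy-atom cutoff
(not stated in the protocol; configurable) and report the fraction of
interval frames in which any ligand heavy atom touches each residue.
Membrane entry is classified by the first frame at which the ligand center
of mass crosses into the slab bounded by the per-frame mean phosphate
heights of the two leaflets, with the side determined by the previous
frame's position.

In the generator, bound ligands follow a discrete-time first-order
mean-reverting process with stationary standard deviation s_b per axis
(default 0.4 A, an empirically tight pocket), free ligands random-walk
laterally with 3 A per-frame steps inside the slab, and one ligand can be
scripted to enter from either side at a chosen frame.

## Dynamical networks

Residue nodes carry the Pearson correlation of C-alpha displacement
vectors (scalar dot-product convention, as in the established network
tools; not 3x3 tensor correlations). Contacts require any heavy-atom pair
within 4.5 A in at least 75% of frames — the convention of the cited
network tooling; the protocol itself states no criterion. Edges exist on
masked pairs with |C| > 0 and carry length -log|C|, so perfectly coupled
pairs are at distance zero; |C| = 0 pairs get no edge rather than a capped
one. Communities come from iterative removal of the highest-betweenness
edge (weighted shortest paths; ties broken by the lexicographically lowest
node pair so runs are reproducible), keeping the partition of maximal
modularity along the removal sequence. Modularity is scored on |C|
coupling strengths, not on the -log|C| path lengths: betweenness needs a
distance-like weight while modularity needs a strength-like one, and
conflating them (as happens when a single weight vector is passed to
generic implementations) selects cuts by an inverted criterion. On graphs
small enough to enumerate, the dendrogram's best cut attains the global
modularity optimum, and the package's removal sequence matches igraph's
edge-betweenness dendrogram.

One caveat discovered while validating: the Pearson correlation of two
*independent random walks* does not vanish with trajectory length (the
classic spurious correlation of integrated processes), so "independent
atoms decorrelate" is only true for stationary displacement processes —
tethered or jittering atoms, which is what protein atoms in a stable fold
are. The tests assert the stationary version.

## Arm motion PCA and tilt/twist

PCA is an eigendecomposition of the 3N x 3N C-alpha coordinate covariance
over a trajectory interval, after least-squares superposition of the
interval on its first frame. Variance fractions are eigenvalue shares;
eigenvectors are oriented so each projection increases over the interval.
Projections are inner products of centered frames with eigenvectors, in
Angstrom of total C-alpha displacement; the mean structure projects to
zero by construction.

Tilt and twist are defined via the spherical angles of the
proximal-to-distal arm axis relative to the membrane normal (z): tilt is
the polar-angle change versus a reference frame, twist the azimuthal
change, both signed, with the azimuth wrapped to (-180, 180]. This is a
convention — the published figures do not define their angle — chosen as
the simplest definition consistent with an outward tilt of the distal arm
and a twist of its distal end. Two properties are worth knowing: a
same-sense twist of all arms is a global rotation about z and is removed
by superposition, so twist modes are visible to PCA only when arms twist
in different senses (the generator's twist-tilt-twist schedule does
exactly that, producing the U-shaped PC1/PC2 path); and the published
~80/65/68 degree maxima and 75%/9% fractions derive from the unavailable
full trajectory, so they appear here only as generator-recovery checks at
those same magnitudes, not as assertions about the original data.

## Pore ions

Ion occupancy counts, per sampled frame (default stride 20 frames =
24 ns), the ions of each species with any atom within 5 A of the region
selection (e.g. the pore-lining backbone), under the minimum-image
convention. The selectivity summary reports the time-averaged
cation:anion ratio (infinite sentinel with a flag when the anion mean is
zero) and per-frame excess. The generator biases cation density by
exp(beta) within 5 A of fixed charge sites and suppresses anions
reciprocally, via rejection sampling; at the default beta = 1 the expected
ratio is e^2 ~ 7.4, and a 50 A box with 40 ions of each species over 60
frames keeps both means comfortably nonzero.

## Functional assays

Delta F/F0 is (F_max - F_0)/F_0 with the maximum searched only at or
after the stimulus time (agonist added at t = 10 s in the default
protocol). The pressure-response fit is the two-state Boltzmann
I/Imax = scale/(1 + exp((P50 - P)/k)) by Levenberg-Marquardt with a signed
slope (activation by suction means negative pressures and negative k) and
a deterministic start from the 50% crossing of linearly interpolated data.
The Mann-Whitney U test uses midranks; for combined n <= 12 the two-tailed
p is exact by enumeration of all group assignments (share of assignments
whose U deviates from n1*n2/2 at least as much as observed), otherwise a
tie-corrected normal approximation with continuity correction. The two
branches agree within 0.02 at n = 6+6 and both reproduce
`stats::wilcox.test` where conventions coincide; the approximate branch's
type-I error at alpha = 0.05 sits near 4.6% over 1000 null replicates of
the n = 10 + 10 design.

## What the generators do and do not emulate

The generators reproduce the *geometry and statistics* the analyses
consume: dome-shaped leaflets with lattice lipids and Gaussian height
noise, tethered-versus-diffusing ligands, block-correlated C-alpha
motion, rigid arms on prescribed schedules, biased ion densities, and
parametric assay readouts. They do not emulate molecular detail —
force-field energetics, lipid chemistry, water, electrostatics beyond the
density bias, or conformational coupling between modules. Passing the
recovery suite therefore demonstrates that the estimators are correct and
well-calibrated on data of the right shape, scale and noise level; it
does not re-derive the original simulations' biological conclusions.

## Problem sizes and numerical choices

Test and benchmark sizes were chosen so the full suite runs in minutes on
one core while keeping every statistical margin wide: 200-draw dome
recovery sweeps (box up to 5*sigma, one lipid per (8 A)^2, ~5,600 lipids
per leaflet at the largest boxes), 100-seed ligand ensembles of 20 ligands
by 120 frames, 50-seed community recoveries of 24 residues by 200 frames,
1000-seed null calibrations. Degenerate inputs are handled explicitly:
flat membranes return an infinite radius sentinel rather than a failed
fit; zero-variance correlation nodes are zeroed and flagged; collinear
superposition selections, empty selections and triclinic boxes are
errors, not silent misbehavior.

## Known limitations

Curvature is reported only at the dome apex of a radial Gaussian — no
mean/Gaussian curvature fields, and strongly non-radial surfaces will fit
poorly (the residual column is the diagnostic). The Girvan-Newman loop
recomputes betweenness after every removal and is meant for
residue-community graphs (hundreds of nodes), not large networks.
Re-imaging wraps whole molecules only; bonds across images within a
molecule are out of scope. Assay ROI segmentation from image stacks is
upstream of this package; traces enter as tables.
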