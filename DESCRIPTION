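Package: piezotraj
Title: Trajectory Analysis of Piezo1 Membrane Mechanics, Ligand Binding and
    Arm Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for molecular-dynamics trajectories of the
    mechanosensitive channel Piezo1 and for the accompanying functional
    assays. Estimates the curvature radius of the membrane dome from lipid
    headgroup positions (periodic tiling, gridding, local-mean smoothing and
    a radial Gaussian surface fit), ranks spontaneously binding ligands by
    windowed RMSF and reports their contact residues and membrane leaflet of
    entry, builds dynamical residue networks from C-alpha motion correlations
    and decomposes them into communities by Girvan-Newman edge removal,
    performs focused principal component analysis of arm tilt and twist
    motions under membrane tension, counts pore ion occupancy, and fits
    calcium-imaging and pressure-clamp readouts (delta F/F0, Boltzmann
    activation, Mann-Whitney U comparisons). A synthetic-data module
    generates every input class with known ground truth so all stages are
    verifiable without the original trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    igraph,
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
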