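#!/usr/bin/env Rscript
# Pore ion occupancy and cation selectivity.
#
# Ions are sampled around fixed negative charge sites (emulating the
# pore-lining glutamate trio): cation density is enhanced and anion density
# suppressed within 5 A of the sites. Per-frame occupancy within 5 A of the
# site region is counted and summarized as a cation:anion ratio.

library(piezotraj)

outdir <- "results/05_pore_ions"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

ib <- make_ion_box(seed = 501, beta = 1)
oc <- ion_occupancy_series(ib$traj, "resname GLU",
                           list(K = "resname K", CL = "resname CL"),
                           cutoff = 5, stride = 1)
write_ion_csv(oc, file.path(outdir, "ion_occupancy.csv"))
s <- selectivity_summary(oc, "K", "CL")
cat(sprintf("mean occupancy within 5 A: K+ %.2f, Cl- %.2f; ratio %.1f\n",
            s$mean_a, s$mean_b,
            if (is.finite(s$ratio)) s$ratio else NA))
cat(sprintf("per-frame cation excess: mean %.2f (anions excluded from the sites)\n",
            mean(s$excess)))

ib0 <- make_ion_box(seed = 502, beta = 0)
oc0 <- ion_occupancy_series(ib0$traj, "resname GLU",
                            list(K = "resname K", CL = "resname CL"),
                            cutoff = 5, stride = 1)
s0 <- selectivity_summary(oc0, "K", "CL")
cat(sprintf("control (no coupling): ratio %.2f (~1 expected)\n", s0$ratio))
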