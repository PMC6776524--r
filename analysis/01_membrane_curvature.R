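#!/usr/bin/env Rscript
# Membrane dome curvature under tension.
#
# A synthetic POPC-like bilayer is generated on the analytic Gaussian dome
# in the regime of the Piezo1 simulations (box 190.1 x 190.1 A^2, dome
# depth -30 A, width 70 A -> analytic |R| ~ 8.2 nm) and flattened linearly,
# emulating the membrane's response to applied tension. The curvature
# pipeline (leaflet assignment, headgroup gridding, dome fit, apex radius)
# is run per frame and leaflet, and the recovered radius is compared with
# the generator's analytic schedule.

library(piezotraj)

outdir <- "results/01_membrane_curvature"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
lipid_cfg <- list(resname = "POPC", head_names = "P", tail_name = "T")

dome <- make_dome_membrane(seed = 101, n_frames = 40, noise_sd = 1,
                           flatten = TRUE)
cs <- curvature_timeseries(dome$traj, lipid_cfg, smooth = FALSE, span = 0.25)
write_curvature_csv(cs, file.path(outdir, "curvature_series.csv"))

truth <- data.frame(time_ns = dome$traj$time,
                    R_true_nm = abs(dome$truth$R_A) / 10)
write.csv(truth, file.path(outdir, "curvature_truth.csv"), row.names = FALSE)

up <- cs[cs$leaflet == "upper" & is.finite(cs$R_nm), ]
m <- merge(up, truth, by = "time_ns")
m <- m[is.finite(m$R_true_nm), ]
cat(sprintf("frames analyzed: %d; initial |R|: %.2f nm (analytic %.2f nm)\n",
            dome$traj$n_frames, up$R_nm[1], truth$R_true_nm[1]))
cat(sprintf("median |R_fit - R_true|/R_true while dome persists: %.2f%%\n",
            100 * median(abs(m$R_nm - m$R_true_nm) / m$R_true_nm)))
cat(sprintf("flattening recovered: fitted R rises monotonically in %d/%d steps\n",
            sum(diff(up$R_nm) > 0), nrow(up) - 1))

# effect of the local-mean smoothing kernel on the fitted radius
one <- make_dome_membrane(seed = 102, n_frames = 1, noise_sd = 1)
cs_s <- curvature_timeseries(one$traj, lipid_cfg, smooth = TRUE, span = NA)
cs_r <- curvature_timeseries(one$traj, lipid_cfg, smooth = FALSE, span = NA)
cat(sprintf("kernel-smoothed fit |R|: %.2f nm vs raw-grid fit %.2f nm (analytic %.2f nm)\n",
            cs_s$R_nm[1], cs_r$R_nm[1], abs(one$truth$R_A[1]) / 10))
cat("note: the uniform kernel attenuates the dome amplitude, biasing R up;\n")
cat("recovery benchmarks therefore run on the unsmoothed grid.\n")
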