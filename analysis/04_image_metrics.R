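#!/usr/bin/env Rscript
# Stage 4: projection images and signal-to-noise ratios.
#
# Re-runs the seeded imaging experiment of stage 3 (deterministic for the
# same seed), projects the deposition grid onto the XY, XZ and YZ planes
# and computes per-material SNR over each volume's footprint. The YZ plane
# sums along the material axis, so its per-volume values are computed from
# the X-restricted subgrid and are not comparable across planes.

library(radiopeek)
dir.create("results", showWarnings = FALSE)

cfg <- study_config(n_events = 1e5, seed = 20260920)
tally <- run_simulation(planar_source(n_events = cfg$n_events),
                        study_volumes(cfg), grid_n = cfg$grid_n,
                        seed = cfg$seed)

for (plane in c("XY", "XZ", "YZ")) {
  pm <- project(tally, plane)
  long <- cbind(expand.grid(i = seq_len(nrow(pm$pixels)),
                            j = seq_len(ncol(pm$pixels))),
                edep_keV = as.vector(pm$pixels))
  write.csv(long, sprintf("results/projection_%s.csv", plane),
            row.names = FALSE)
}

rep <- snr_report(tally)
write.csv(rep, "results/snr.csv", row.names = FALSE)

wide <- reshape(rep[rep$volume != "(whole image)",
                    c("volume", "plane", "mean", "sd", "snr")],
                direction = "wide", idvar = "volume", timevar = "plane")
cat("Per-material SNR of the energy-deposition images:\n")
print(wide, row.names = FALSE, digits = 3)
cat("\nDense composites produce bright, well-defined footprints; their",
    "SNR reflects both the deposit magnitude and the depth profile of",
    "absorption within each cube.\n")
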