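#!/usr/bin/env Rscript
# Step 1 -- generate the synthetic experiment.
#
# Emulates the physical campaign: 2 shaft materials x 4 circumnutation
# frequencies x 5 replicates of penetration-force traces (1 Hz, 1 cm/h,
# 10 mm), projected deflection-angle series (1/min), and one CT phantom
# per condition class (penetrated + unpenetrated reference). Everything
# is seeded; outputs land under results/raw/.

suppressPackageStartupMessages(library(circumpen))

seed <- 42L
out <- "results/raw"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- generator_config(seed = seed)

## force traces
sim <- gen_force_traces(cfg)
write.csv(sim$traces, file.path(out, "traces.csv"), row.names = FALSE)
write.csv(sim$meta, file.path(out, "meta.csv"), row.names = FALSE)
cat(sprintf("traces: %d samples over %d treatments x %d replicates\n",
            nrow(sim$traces), nrow(sim$meta), cfg$n_replicates))

## deflection-angle series, one file per treatment/replicate stack
angles <- do.call(rbind, lapply(seq_len(nrow(cfg$deflection_table)),
                                function(r) {
  tr <- cfg$deflection_table[r, ]
  do.call(rbind, lapply(seq_len(cfg$n_replicates), function(rep_i) {
    ser <- gen_deflection_series(cfg, tr$material, tr$f,
                                 seed = seed + 1000L + 101L * r + rep_i)
    cbind(ser, replicate = rep_i,
          treatment = sprintf("%s_f%d", tr$material, tr$f))
  }))
}))
write.csv(angles, file.path(out, "angles.csv"), row.names = FALSE)
cat(sprintf("angles: %d samples (%s)\n", nrow(angles),
            paste(unique(angles$treatment), collapse = ", ")))

## CT phantoms: one penetrated, one unpenetrated reference
ph <- gen_ct_phantom(cfg, seed = seed + 7L)
write_voxel_volume(ph$binary, file.path(out, "phantom.tif"))
ref <- gen_ct_phantom(cfg, reference = TRUE, seed = seed + 8L)
write_voxel_volume(ref$binary, file.path(out, "phantom_ref.tif"))
gt <- ph$ground_truth
jsonlite::write_json(
  list(imprint_volume_mm3 = gt$imprint_volume_mm3,
       imprint_radius_mm = gt$imprint_radius_mm,
       tip_depth_mm = gt$tip_depth_mm,
       eps_vis_background = gt$eps_vis_background,
       halo_amplitude = gt$halo_amplitude,
       halo_lambda_mm = gt$halo_lambda_mm,
       seed = gt$seed),
  file.path(out, "phantom_truth.json"), auto_unbox = TRUE, digits = NA)
cat(sprintf("phantom: %s voxels, imprint %.2f mm^3 (truth)\n",
            paste(dim(ph$binary$values), collapse = "x"),
            gt$imprint_volume_mm3))
cat("done: raw data under", out, "\n")
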