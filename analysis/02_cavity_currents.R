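#!/usr/bin/env Rscript
# Breathing-driven ascitic currents in the synthetic peritoneal cavity:
# regular (6.0 cm, 0.37 Hz) versus energetic (8.0 cm, 1.0 Hz) breathing,
# three diaphragmatic cycles each, reporting domain velocity metrics and
# per-ovary FSS over the final cycle.
#
# Finding (desk-scale 2D cavity, defaults): the active preset exceeds the
# regular preset in mean and peak speed and in mean and peak ovary FSS;
# left and right ovary metrics agree to roundoff on the mirror-symmetric
# cavity; the cycle-to-cycle periodicity residual shrinks, consistent
# with approach to a periodic state after three cycles.
#
# Outputs: results/cavity_<preset>/ (summary.json, patch_series.csv, VTU
# series, run log), results/cavity_metrics.csv, results/fig_ovary_fss_*.png.

suppressPackageStartupMessages(library(asciflow))
dir.create("results", showWarnings = FALSE)

rows <- list()
for (nm in c("regular", "active")) {
  cfg <- run_config(list(
    mode = "cavity",
    preset = nm,
    solver = list(steps_per_cycle = 80, max_nonlinear_iterations = 2,
                  nonlinear_tolerance = 1e-4, sd_constant = 0.5,
                  snapshot_stride = 4)))
  out <- run(cfg, file.path("results", paste0("cavity_", nm)))
  s <- out$summary
  report(s, file.path("results", sprintf("fig_ovary_fss_%s.png", nm)))
  rows[[nm]] <- data.frame(
    preset = nm,
    mean_speed_cm_s = s$mean_speed_cm_s,
    peak_speed_cm_s = s$peak_speed_cm_s,
    ovary_left_mean_fss = s$patch_metrics$ovary_left$mean_fss,
    ovary_left_peak_fss = s$patch_metrics$ovary_left$peak_fss,
    ovary_right_mean_fss = s$patch_metrics$ovary_right$mean_fss,
    ovary_right_peak_fss = s$patch_metrics$ovary_right$peak_fss,
    periodicity_residual = s$periodicity_residual,
    max_volume_drift = s$max_volume_drift)
}
df <- do.call(rbind, rows)
write.csv(df, "results/cavity_metrics.csv", row.names = FALSE)
print(df, digits = 4)
cat("\nactive > regular in all four shear/velocity metrics:",
    all(df[2, 2:7] > df[1, 2:7]), "\n")
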