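#!/usr/bin/env Rscript
# Build the synthetic study inputs: filament fields across a surface
# concentration and order grid, one two-channel contraction series per
# mode, and the scalar FRAP / binding traces. Ground truth goes to
# results/ as JSON/CSV; images stay in memory for the downstream steps
# (each step regenerates deterministically from the seeds written here).

suppressMessages(library(macnet))
dir.create("results", showWarnings = FALSE)

conditions <- expand.grid(n_filaments = c(25, 50, 100, 200),
                          orientation_kappa = c(0, 1, 4),
                          seed = 1:5)
write.csv(conditions, "results/01_field_conditions.csv", row.names = FALSE)
cat(sprintf("field grid: %d conditions (n x kappa x seed)\n", nrow(conditions)))

# one representative field with full ground truth on disk
p <- synth_params(image_size_px = c(256L, 256L), n_filaments = 100,
                  orientation_kappa = 1, psf_sigma_um = 0.2,
                  background = 20, seed = 1)
field <- sample_filament_field(p)
write_truth_json(field, "results/01_example_truth.json")
cat(sprintf("example field: %d filaments, %d true crossings, analytic q = %.3f\n",
            length(field$filaments), nrow(field$node_coords),
            true_order_parameter(field)))

# contraction series ground truth (imposed flow) per mode
for (mode in c("global", "partial", "none")) {
  cp <- contraction_params(n_frames = 22L, frame_interval_s = 10,
                           aster_centers = rbind(c(6.4, 12.7), c(19, 12.7)),
                           v0_um_per_s = 0.08, capture_radius_um = 10,
                           mode = mode, seed = 1001L)
  pf <- synth_params(image_size_px = c(128L, 128L), pixel_size_um = 0.2,
                     n_filaments = 60, psf_sigma_um = 0.3,
                     line_amplitude = 120, background = 20, seed = 1)
  s <- generate_contraction_series(sample_filament_field(pf,
                                                         compute_nodes = FALSE),
                                   cp)
  write_flow_csv(s$flow, sprintf("results/01_flow_%s.csv", mode))
  cat(sprintf("%s series: %d frames, imposed |v| max %.3f um/s\n",
              mode, n_frames(s$actin),
              max(sqrt(s$flow[[1]]$u_um_s^2 + s$flow[[1]]$v_um_s^2))))
}

# scalar traces
frap <- generate_frap_trace(3, 5, immobile_fraction = 0.05,
                            frame_time_s = 0.5, n_frames = 120L,
                            noise_sd = 0.02, seed = 5)
write.csv(data.frame(time_s = frap$times_s, intensity = frap$spot_intensity),
          "results/01_frap_trace.csv", row.names = FALSE)
rifs <- generate_rifs_trace(data.frame(duration_s = c(300, 600),
                                       dOT_nm = c(0, 6.0)),
                            noise_sd = 0.1, seed = 6)
write.csv(data.frame(time_s = rifs$times_s, dOT_nm = rifs$dOT_nm),
          "results/01_rifs_trace.csv", row.names = FALSE)
cat("wrote FRAP and binding traces\n")
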