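#!/usr/bin/env Rscript
# Membrane-interface scalar measurements: binding-step amplitude and layer
# thickness from the optical-thickness trace, and the FRAP diffusion fit.

suppressMessages(library(macnet))
dir.create("results", showWarnings = FALSE)

rifs <- read_trace_csv("results/01_rifs_trace.csv", "rifs")
amp <- binding_amplitude(rifs, baseline_window = c(0, 290),
                         plateau_window = c(400, 900))
d_prot <- ot_to_thickness(amp, n_prot = 1.455)
cat(sprintf("binding step: dOT = %.2f nm -> layer thickness %.2f nm (n = 1.455)\n",
            amp, d_prot))

# reference thicknesses at the two reported plateau levels
cat(sprintf("plateau 6.0 nm -> %.1f nm; plateau 4.7 nm -> %.1f nm\n",
            signif(ot_to_thickness(6.0), 2), signif(ot_to_thickness(4.7), 2)))

frap <- read_trace_csv("results/01_frap_trace.csv", "frap",
                       bleach_radius_um = 5, bleach_index = 6L)
fit <- fit_frap(frap)
cat(sprintf("FRAP fit: D = %.2f um^2/s, immobile fraction %.3f (generated: 3.0, 0.05)\n",
            fit$D_um2_per_s, fit$immobile_fraction))

write.csv(data.frame(
  quantity = c("binding_step_nm", "layer_thickness_nm", "D_um2_per_s",
               "immobile_fraction"),
  value = c(amp, d_prot, fit$D_um2_per_s, fit$immobile_fraction)
), "results/05_interface.csv", row.names = FALSE)
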