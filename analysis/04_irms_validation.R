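#!/usr/bin/env Rscript
# Validate the GC/IRMS delta-18O correction chain on synthetic sequences
# with injected blank, linearity, drift and scale-offset artifacts, and
# check the control-experiment generator against its documented bounds.

suppressPackageStartupMessages(library(photokie))
dir.create("results", showWarnings = FALSE)

set.seed(42)
runs <- lapply(1:50, function(i) {
  truth <- runif(6, 20, 80)
  art <- list(blank_amplitude = runif(1, 0.05, 0.4),
              blank_delta = runif(1, -5, 10),
              linearity_slope = runif(1, -0.03, 0.03),
              drift_slope = runif(1, -0.01, 0.01),
              calibration_offset = runif(1, -1, 1))
  for (sigma in c(0, 0.05)) {
    seq0 <- generate_irms_sequence(truth, art,
                                   noise_model(sigma_delta = sigma, seed = i))
    corr <- correct_sequence(seq0)
    smp <- corr$kind == "sample"
    rms <- sqrt(mean((corr$corrected_delta[smp] - truth)^2))
    if (sigma == 0) rms0 <- rms else rms1 <- rms
  }
  data.frame(run = i, rms_noise_free = rms0, rms_sigma_0.05 = rms1)
})
rms <- do.call(rbind, runs)
write.csv(rms, "results/irms_roundtrip_rms.csv", row.names = FALSE)

cat(sprintf("Noise-free artifact inversion: max RMS %.4f permil over 50 runs.\n",
            max(rms$rms_noise_free)))
cat(sprintf("With 0.05 permil measurement noise: median RMS %.3f permil.\n",
            median(rms$rms_sigma_0.05)))

ctl <- do.call(rbind, lapply(1:100, function(seed) {
  k <- c("no_sensitizer", "no_probe", "dark")[seed %% 3 + 1]
  d <- generate_controls(k, noise_model(2, 0.5, seed = seed))
  data.frame(seed = seed, kind = k, f_final = min(d$f),
             ddelta = max(abs(d$delta18O_permil - d$delta18O_permil[1])))
}))
write.csv(ctl, "results/control_bounds.csv", row.names = FALSE)
cat(sprintf("Controls over 100 seeds: min final f = %.3f (bound 0.94), max |delta drift| = %.2f permil (bound 0.7).\n",
            min(ctl$f_final), max(ctl$ddelta)))
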