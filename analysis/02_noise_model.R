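#!/usr/bin/env Rscript
# Noise characterization of the substrate presets: synthesize 0-mV and
# under-bias baseline traces for quartz and Si, estimate their PSDs, refit
# the four-term model, and tabulate band-limited and filtered RMS noise.
#
# Writes results/noise_summary.tsv and results/psd_<preset>.tsv.

suppressPackageStartupMessages(library(poresignal))
dir.create("results", showWarnings = FALSE)

fs <- 250e3
presets <- c("quartz0mV", "quartzBias", "si0mV", "siBias")

rows <- lapply(seq_along(presets), function(i) {
  nm <- presets[i]
  p <- noise_preset(nm)
  x <- synth_noise(p, fs, 4 * fs, seed = 100 + i)
  sp <- estimate_psd(x, fs)
  # archive a log-spaced subsample; the full 8192-bin grid is redundant
  keep <- unique(round(10^seq(0, log10(length(sp$freqs_Hz)),
                              length.out = 400)))
  write_spectrum(noise_spectrum(sp$freqs_Hz[keep], sp$psd_A2_per_Hz[keep]),
                 sprintf("results/psd_%s.tsv", nm))
  fit <- fit_noise_model(sp, fit_range_Hz = c(3 * fs / 2^14, 1e5))
  filt <- bessel_lowpass(trace_recording(x[1:fs] * 1e12, fs))
  data.frame(preset = nm,
             rms_band_pA = rms_from_psd(p, c(1, 1e4)),
             rms_filtered_pA = sd(filt$samples_pA),
             A_fit = fit$A, beta_fit = fit$beta, B_fit = fit$B,
             C_fit = fit$C, D_fit = fit$D)
})
tab <- do.call(rbind, rows)
write.table(format(tab, digits = 4), "results/noise_summary.tsv",
            sep = "\t", row.names = FALSE, quote = FALSE)

cat("band RMS (1 Hz-10 kHz) and 10-kHz-filtered trace RMS, in pA:\n")
print(tab[, 1:3], row.names = FALSE, digits = 3)
cat("\nquartz sits ~7x below Si at rest, matching the preset construction;\n")
cat("refitted flicker exponents:",
    sprintf("%.2f", tab$beta_fit), "\n")
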