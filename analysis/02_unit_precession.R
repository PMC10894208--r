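#!/usr/bin/env Rscript
# Unit-level analysis: spike extraction and the precession classification
# framework on a synthetic population.
#
# Part A runs the preprocessing chain on one contaminated extracellular
# trace: spectral interpolation of the 10 Hz stimulation artifact, 300-3000
# Hz zero-phase band-pass, 4-sigma threshold detection, and cluster SNR.
# Part B builds a 60-unit population with planted phase behaviour
# (stable / drifting / unlocked), assigns stimulation phases, computes
# 20-window circular tracks pooled over 4 blocks, classifies every unit,
# and tabulates the population outcome.

suppressPackageStartupMessages(library(acprecess))
dir.create("results", showWarnings = FALSE)
set.seed(2)

## Part A: one channel, artifact in, spikes out ---------------------------
message("Part A: spike extraction from an artifact-contaminated trace")
fx <- gen_extracellular_trace(duration = 8, sampling_rate = 20000,
                              n_spikes = 60, amplitude_sigma = 8,
                              artifact_amplitude = 40, artifact_freq = 10,
                              seed = 201)
clean <- remove_artifact_spectral(fx$recording, c(10, 20, 30), halfwidth = 0.5)
det <- detect_spikes(bandpass(clean))
matched <- vapply(fx$spike_times, function(tt) {
  any(abs(det$spike_times - tt) * 20000 <= 2)
}, logical(1))
message(sprintf("  %d/%d planted spikes recovered (%d detections, SNR %.2f, threshold %.2f)",
                sum(matched), length(matched), length(det$spike_times),
                compute_snr(det), det$threshold))
write_spikes_csv(det, "results/unit_detected_spikes.csv")

## Part B: population classification --------------------------------------
message("Part B: classifying 60 synthetic units (4 blocks of 360 s each)")
truth <- data.frame(unit = seq_len(60),
                    kind = rep(c("stable", "ccw", "cw", "unlocked"),
                               c(20, 12, 12, 16)))
truth$drift <- ifelse(truth$kind == "ccw", runif(60, 30, 60),
                      ifelse(truth$kind == "cw", -runif(60, 30, 60), 0))
truth$kappa <- ifelse(truth$kind == "unlocked", 0, runif(60, 2, 4))
coverage <- (20 - 1) * 12 / 360

cls <- vector("list", 60)
for (u in seq_len(60)) {
  spikes <- list(); phases <- list()
  for (b in 1:4) {
    g <- gen_spike_train(360, 1.5, truth$kappa[u], mu0 = runif(1, 0, 360),
                         drift = truth$drift[u] / coverage,
                         stim_frequency = 10, seed = 300 + 17 * u + b)
    spikes[[b]] <- g$spike_times
    phases[[b]] <- g$phases_deg
  }
  tr <- window_track(spikes, phases, windowing_scheme(132, 12, 20, 360),
                     unit_id = sprintf("unit%02d", u))
  cls[[u]] <- classify_precession(tr)
}
pop <- summarize_population(cls)
write.csv(pop, "results/unit_population_summary.csv", row.names = FALSE)
per_unit <- data.frame(
  unit = truth$unit, planted = truth$kind,
  label = vapply(cls, function(x) x$label, character(1)),
  total_shift = vapply(cls, function(x) x$total_shift, numeric(1)),
  r_circlin = vapply(cls, function(x) x$r_circlin, numeric(1)))
write.csv(per_unit, "results/unit_classifications.csv", row.names = FALSE)
print(pop)
agree <- mean((per_unit$planted == "ccw" & per_unit$label == "counter-clockwise") |
              (per_unit$planted == "cw" & per_unit$label == "clockwise") |
              (per_unit$planted == "stable" & per_unit$label == "stable") |
              (per_unit$planted == "unlocked" & per_unit$label == "non-responsive"))
message(sprintf("Planted behaviour recovered for %.0f%% of units", 100 * agree))
message("Wrote results/unit_detected_spikes.csv, results/unit_classifications.csv, results/unit_population_summary.csv")
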