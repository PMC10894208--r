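# Trace preprocessing and spike extraction: robust noise estimate, zero-phase
# band-pass, spectral artifact interpolation, threshold detection, cluster SNR.

band_power <- function(x, fs, f0, hw = 0.5) {
  sp <- stats::spec.pgram(stats::ts(x, frequency = fs), plot = FALSE,
                          taper = 0, detrend = FALSE)
  sel <- sp$freq >= f0 - hw & sp$freq <= f0 + hw
  mean(sp$spec[sel])
}

test_that("noise sigma recovers the Gaussian SD and resists outliers", {
  set.seed(1)
  x <- rnorm(1e6, 0, 2)
  expect_equal(estimate_noise_sigma(x), 2, tolerance = 0.01)
  expect_equal(estimate_noise_sigma(c(3, -3, 3, -3)), 3 / 0.6745)
  expect_equal(estimate_noise_sigma(rep(0, 100)), 0)
  expect_error(estimate_noise_sigma(numeric(0)), "empty")
  # 1% contamination at 100 sigma barely moves the estimate; sd() explodes
  x2 <- x
  idx <- sample(length(x2), length(x2) / 100)
  x2[idx] <- 200 * sign(x2[idx])
  expect_lt(abs(estimate_noise_sigma(x2) - 2) / 2, 0.05)
  expect_gt(sd(x2) / 2, 10)
})

test_that("cluster SNR matches the hand-computed example and its invariances", {
  wf <- rbind(c(0, 4, 0), c(0, 6, 0))
  # residuals (0, -1, 0) and (0, 1, 0); sample SD over snippet = 0.57735
  expect_equal(compute_snr(wf), 4.330127, tolerance = 1e-6)
  expect_error(compute_snr(rbind(c(1, 2, 3), c(1, 2, 3))), "degenerate")
  expect_error(compute_snr(matrix(1:3, 1)), "at least 2")
  set.seed(2)
  wf2 <- matrix(rnorm(10 * 32), 10) + outer(rep(1, 10), sin(1:32))
  expect_equal(compute_snr(wf2 * 3.7), compute_snr(wf2), tolerance = 1e-12)
})

test_that("zero-phase Butterworth band-pass has the specified response", {
  fs <- 20000
  t <- seq(0, 1, by = 1 / fs)
  cfg <- detection_config()
  inband <- continuous_recording(sin(2 * pi * 1000 * t), fs)
  out <- bandpass(inband, cfg)
  mid <- seq(fs / 4, 3 * fs / 4)
  expect_equal(max(abs(out$samples[mid])), 1, tolerance = 0.05)
  low <- bandpass(continuous_recording(sin(2 * pi * 10 * t), fs), cfg)
  expect_lt(max(abs(low$samples[mid])), 10^(-40 / 20))
  dc <- bandpass(continuous_recording(rep(1, fs), fs), cfg)
  expect_lt(max(abs(dc$samples[mid])), 1e-3)
  expect_error(bandpass(continuous_recording(rnorm(100), 1000), cfg),
               "Nyquist")
})

test_that("spectral interpolation flattens artifact bands and preserves clean traces", {
  set.seed(3)
  fs <- 1000
  t <- seq(0, 20 - 1 / fs, by = 1 / fs)
  x <- sin(2 * pi * 10 * t) + rnorm(length(t), 0, 0.01)
  rec <- continuous_recording(x, fs)
  cleaned <- remove_artifact_spectral(rec, 10, halfwidth = 0.5)
  expect_equal(length(cleaned$samples), length(x))
  p_in <- band_power(cleaned$samples, fs, 10)
  p_nb <- band_power(cleaned$samples, fs, 13)
  expect_lt(10 * log10(p_in / p_nb), 3)   # within 3 dB of neighbours
  # identity on empty target list
  expect_identical(remove_artifact_spectral(rec, numeric(0))$samples, x)
  # two artifacts suppressed at once
  x2 <- sin(2 * pi * 10 * t) + 0.7 * sin(2 * pi * 20 * t) +
    rnorm(length(t), 0, 0.01)
  cl2 <- remove_artifact_spectral(continuous_recording(x2, fs), c(10, 20))
  expect_lt(10 * log10(band_power(cl2$samples, fs, 10) /
                         band_power(cl2$samples, fs, 15)), 3)
  expect_lt(10 * log10(band_power(cl2$samples, fs, 20) /
                         band_power(cl2$samples, fs, 24)), 3)
  expect_error(remove_artifact_spectral(rec, 499.9), "Nyquist")
})

test_that("threshold detection recovers planted templates with timing accuracy", {
  fx <- gen_extracellular_trace(duration = 6, sampling_rate = 20000,
                                n_spikes = 40, amplitude_sigma = 8, seed = 4)
  det <- detect_spikes(bandpass(fx$recording))
  err <- vapply(fx$spike_times, function(tt) {
    min(abs(det$spike_times - tt)) * 20000
  }, numeric(1))
  expect_true(all(err <= 2))          # every planted spike recovered
  # spurious events bounded by the Gaussian 4-sigma exceedance rate
  n_extra <- length(det$spike_times) - 40
  bound <- 2 * pnorm(-4) * 6 * 20000
  expect_gte(n_extra, 0)
  expect_lte(n_extra, 2 * bound + 5)
  expect_equal(ncol(det$waveforms), 32)
  # alignment: extremum at index pre_samples + 1
  peaks <- apply(abs(det$waveforms), 1, which.max)
  expect_true(all(peaks == 9))
  expect_gt(compute_snr(det), 3)
})

test_that("detection on pure noise stays below the Gaussian exceedance bound", {
  set.seed(5)
  fs <- 20000
  rec <- continuous_recording(rnorm(10 * fs), fs)
  det <- detect_spikes(rec, detection_config(lambda_factor = 4))
  # expected samples above 4 sigma (both signs); each yields at most one event
  bound <- 2 * pnorm(-4) * 10 * fs
  expect_lt(length(det$spike_times), 2 * bound + 10)
})

test_that("detection recall and precision stay >= 95% at 6 sigma templates", {
  recall_hits <- 0; matched_det <- 0; n_det <- 0; n_true <- 0
  for (sd in 6:8) {
    fx <- gen_extracellular_trace(duration = 3, sampling_rate = 20000,
                                  n_spikes = 100, amplitude_sigma = 6,
                                  seed = sd)
    det <- detect_spikes(bandpass(fx$recording))
    n_true <- n_true + 100
    n_det <- n_det + length(det$spike_times)
    recall_hits <- recall_hits + sum(vapply(fx$spike_times, function(tt) {
      any(abs(det$spike_times - tt) * 20000 <= 5)
    }, logical(1)))
    matched_det <- matched_det + sum(vapply(det$spike_times, function(tt) {
      any(abs(fx$spike_times - tt) * 20000 <= 5)
    }, logical(1)))
  }
  expect_gte(recall_hits / n_true, 0.95)   # recall
  expect_gte(matched_det / n_det, 0.95)    # precision
})

test_that("artifact removal restores spike times hidden under a strong AC artifact", {
  fs <- 20000
  clean <- gen_extracellular_trace(duration = 6, sampling_rate = fs,
                                   n_spikes = 30, amplitude_sigma = 8,
                                   seed = 6)
  dirty <- clean
  tt <- (seq_along(dirty$recording$samples) - 1) / fs
  dirty$recording$samples <- dirty$recording$samples +
    50 * sin(2 * pi * 10 * tt)
  det_clean <- detect_spikes(bandpass(clean$recording))
  fixed <- remove_artifact_spectral(dirty$recording, 10, halfwidth = 0.5)
  det_fixed <- detect_spikes(bandpass(fixed))
  matched <- vapply(det_clean$spike_times, function(x) {
    any(abs(det_fixed$spike_times - x) * fs <= 2)
  }, logical(1))
  expect_gte(mean(matched), 0.95)
})

test_that("recordings round-trip through float32 binary plus JSON sidecar", {
  set.seed(7)
  rec <- continuous_recording(rnorm(1000), 30000, "chA")
  f <- withr::local_tempfile()
  write_recording_f32(rec, f)
  back <- read_recording_f32(f)
  expect_equal(back$sampling_rate, 30000)
  expect_equal(back$channel_id, "chA")
  expect_equal(back$samples, rec$samples, tolerance = 1e-6)
  det <- detect_spikes(continuous_recording(c(rep(0, 100), 10, rep(0, 100),
                                              -8, rep(0, 100)), 1000),
                       detection_config(band_low = 1, band_high = 499),
                       sigma = 1)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_spikes_csv(det, csv)
  df <- read.csv(csv)
  expect_equal(nrow(df), 2)
  expect_equal(df$polarity, c(1, -1))
})
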