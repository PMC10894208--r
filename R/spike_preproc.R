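# Continuous-trace preprocessing and spike extraction: spectral-interpolation
# artifact removal, zero-phase Butterworth band-pass, robust noise estimate,
# amplitude-threshold detection with snippet extraction, and cluster SNR.

#' Continuous extracellular recording
#'
#' @param samples numeric voltage trace (consistent arbitrary units).
#' @param sampling_rate Hz, `> 0`.
#' @param channel_id label.
#' @return object of class `continuous_recording`.
#' @export
continuous_recording <- function(samples, sampling_rate, channel_id = "ch1") {
  stopifnot(is.numeric(samples), length(samples) >= 1,
            is.numeric(sampling_rate), sampling_rate > 0)
  structure(list(samples = as.numeric(samples),
                 sampling_rate = as.numeric(sampling_rate),
                 channel_id = as.character(channel_id)),
            class = "continuous_recording")
}

#' @export
print.continuous_recording <- function(x, ...) {
  cat(sprintf("<continuous_recording> %s: %d samples @ %g Hz (%.2f s)\n",
              x$channel_id, length(x$samples), x$sampling_rate,
              length(x$samples) / x$sampling_rate))
  invisible(x)
}

#' Read / write a recording as raw float32 + JSON sidecar
#'
#' The binary file is little-endian float32; the sidecar `<path>.json` holds
#' `{"sampling_rate_hz": ..., "channel_id": ...}`.
#'
#' @param path binary file path (sidecar at `paste0(path, ".json")`).
#' @return a [continuous_recording()].
#' @export
read_recording_f32 <- function(path) {
  meta <- jsonlite::fromJSON(paste0(path, ".json"))
  n <- file.info(path)$size / 4
  con <- file(path, "rb")
  on.exit(close(con))
  x <- readBin(con, "numeric", n = n, size = 4, endian = "little")
  continuous_recording(x, meta$sampling_rate_hz,
                       meta$channel_id %||% "ch1")
}

#' @rdname read_recording_f32
#' @param rec a [continuous_recording()] to write.
#' @export
write_recording_f32 <- function(rec, path) {
  stopifnot(inherits(rec, "continuous_recording"))
  con <- file(path, "wb")
  writeBin(as.numeric(rec$samples), con, size = 4, endian = "little")
  close(con)
  jsonlite::write_json(list(sampling_rate_hz = rec$sampling_rate,
                            channel_id = rec$channel_id),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Spike-detection configuration
#'
#' @param lambda_factor threshold multiplier on the noise SD (default 4).
#' @param band_low,band_high band-pass corners, Hz (defaults 300-3000).
#' @param filter_order Butterworth order (default 4).
#' @param pre_samples,post_samples snippet samples before/after the aligned
#'   extremum (defaults 8 and 24; total 32).
#' @param censor_ms refractory/censor window after each detection, ms;
#'   defaults to the snippet span so one waveform (including its filtered
#'   rebound lobe) cannot fire twice.
#' @return object of class `detection_config`.
#' @export
detection_config <- function(lambda_factor = 4, band_low = 300,
                             band_high = 3000, filter_order = 4,
                             pre_samples = 8, post_samples = 24,
                             censor_ms = 1.6) {
  stopifnot(lambda_factor > 0, band_low > 0, band_high > band_low,
            filter_order >= 1, pre_samples >= 1, post_samples >= 1,
            censor_ms >= 0)
  structure(list(lambda_factor = lambda_factor, band_low = band_low,
                 band_high = band_high, filter_order = filter_order,
                 pre_samples = as.integer(pre_samples),
                 post_samples = as.integer(post_samples),
                 censor_ms = censor_ms),
            class = "detection_config")
}

#' Remove narrow-band artifacts by spectral interpolation
#'
#' Replaces the amplitude spectrum inside each target band
#' `f0 +/- halfwidth` by linear interpolation of the mean amplitudes in the
#' flanking bands of the same width, preserving phases, then inverts the FFT.
#' Used to strip the AC stimulation artifact (and harmonics) before spike
#' sorting.
#'
#' @param rec a [continuous_recording()].
#' @param target_freqs artifact frequencies, Hz (may be empty).
#' @param halfwidth half-width of each replaced band, Hz.
#' @return a cleaned [continuous_recording()] of identical length.
#' @export
remove_artifact_spectral <- function(rec, target_freqs, halfwidth = 0.5) {
  stopifnot(inherits(rec, "continuous_recording"), halfwidth > 0)
  if (length(target_freqs) == 0) return(rec)
  fs <- rec$sampling_rate
  nyq <- fs / 2
  if (any(target_freqs + halfwidth >= nyq)) {
    stop("remove_artifact_spectral: target band exceeds the Nyquist frequency")
  }
  n <- length(rec$samples)
  X <- stats::fft(rec$samples)
  freqs <- (0:(n - 1)) * fs / n
  amp <- Mod(X)
  for (f0 in target_freqs) {
    band <- which(freqs >= f0 - halfwidth & freqs <= f0 + halfwidth)
    if (length(band) == 0) next
    loflank <- which(freqs >= f0 - 3 * halfwidth & freqs < f0 - halfwidth)
    hiflank <- which(freqs > f0 + halfwidth & freqs <= f0 + 3 * halfwidth)
    # flank means on each side; fall back to the other side at the edge
    alo <- if (length(loflank)) mean(amp[loflank]) else NA_real_
    ahi <- if (length(hiflank)) mean(amp[hiflank]) else NA_real_
    if (is.na(alo)) alo <- ahi
    if (is.na(ahi)) ahi <- alo
    w <- seq(0, 1, length.out = length(band))
    target_amp <- alo * (1 - w) + ahi * w
    scale <- ifelse(amp[band] > 0, target_amp / amp[band], 0)
    X[band] <- X[band] * scale
    # mirror bins keep conjugate symmetry (skip DC, handle shared Nyquist bin)
    mirror <- n - band + 2L
    ok <- band > 1L & mirror >= 1L & mirror <= n & mirror != band
    X[mirror[ok]] <- Conj(X[band[ok]])
  }
  cleaned <- Re(stats::fft(X, inverse = TRUE)) / n
  continuous_recording(cleaned, fs, rec$channel_id)
}

#' Zero-phase Butterworth band-pass filter
#'
#' Forward-backward (zero-phase) Butterworth band-pass of the configured
#' order, so spike times are not biased by filter delay.
#'
#' @param rec a [continuous_recording()].
#' @param cfg a [detection_config()].
#' @return filtered [continuous_recording()].
#' @export
bandpass <- function(rec, cfg = detection_config()) {
  stopifnot(inherits(rec, "continuous_recording"))
  nyq <- rec$sampling_rate / 2
  if (cfg$band_high >= nyq) {
    stop("bandpass: band edge at or above the Nyquist frequency")
  }
  bf <- signal::butter(cfg$filter_order,
                       c(cfg$band_low, cfg$band_high) / nyq, type = "pass")
  y <- signal::filtfilt(bf, rec$samples)
  continuous_recording(y, rec$sampling_rate, rec$channel_id)
}

#' Robust background-noise SD estimate
#'
#' `sigma_n = median(|x|) / 0.6745`; for Gaussian noise this recovers the SD
#' while staying nearly insensitive to the spikes themselves, unlike the
#' ordinary standard deviation.
#'
#' @param rec a [continuous_recording()] (or numeric vector).
#' @return scalar noise SD estimate.
#' @export
estimate_noise_sigma <- function(rec) {
  x <- if (inherits(rec, "continuous_recording")) rec$samples else rec
  if (length(x) == 0) stop("estimate_noise_sigma: empty trace")
  stats::median(abs(x)) / 0.6745
}

#' Detect spikes by amplitude thresholding
#'
#' Threshold `th = lambda * sigma_n` on the absolute filtered trace; each
#' suprathreshold event is aligned to its local extremum (negative or
#' positive peak, whichever dominates), a censor window suppresses double
#' detections, and a fixed-length snippet (`pre + post` samples, extremum at
#' index `pre_samples + 1`) is cut. Events whose snippet would run past a
#' trace end are dropped and counted.
#'
#' @param rec a band-passed [continuous_recording()].
#' @param cfg a [detection_config()].
#' @param sigma optional noise SD; default re-estimated from `rec`.
#' @return object of class `waveform_cluster`: `spike_times` (s, at the
#'   extremum), `waveforms` (matrix spikes x snippet), `polarity` (+1/-1),
#'   `threshold`, `sigma`, `n_dropped_edge`.
#' @export
detect_spikes <- function(rec, cfg = detection_config(), sigma = NULL) {
  stopifnot(inherits(rec, "continuous_recording"))
  x <- rec$samples
  fs <- rec$sampling_rate
  if (is.null(sigma)) sigma <- estimate_noise_sigma(rec)
  th <- cfg$lambda_factor * sigma
  censor <- max(1L, round(cfg$censor_ms / 1000 * fs))
  above <- abs(x) > th
  idx <- which(above)
  snip_len <- cfg$pre_samples + cfg$post_samples
  times <- numeric(0); peaks <- integer(0); pols <- integer(0)
  dropped <- 0L
  last_peak <- -Inf
  i <- 1L
  n <- length(x)
  while (i <= length(idx)) {
    start <- idx[i]
    if (start <= last_peak + censor) { i <- i + 1L; next }
    # local extremum within one censor window of the crossing
    win_end <- min(start + censor, n)
    seg <- x[start:win_end]
    k <- which.max(abs(seg))
    peak <- start + k - 1L
    # extend while the extremum sits on the window edge (rising event)
    while (peak == win_end && win_end < n) {
      win_end <- min(win_end + censor, n)
      seg <- x[start:win_end]
      k <- which.max(abs(seg))
      peak <- start + k - 1L
    }
    if (peak - cfg$pre_samples < 1L || peak + cfg$post_samples - 1L > n) {
      dropped <- dropped + 1L
    } else {
      peaks <- c(peaks, peak)
      pols <- c(pols, as.integer(sign(x[peak])))
    }
    last_peak <- peak
    i <- i + 1L
  }
  if (length(peaks)) {
    wf <- t(vapply(peaks, function(p) {
      x[(p - cfg$pre_samples):(p + cfg$post_samples - 1L)]
    }, numeric(snip_len)))
    times <- (peaks - 1) / fs
  } else {
    wf <- matrix(numeric(0), nrow = 0, ncol = snip_len)
  }
  structure(list(spike_times = times, waveforms = wf, polarity = pols,
                 threshold = th, sigma = sigma,
                 n_dropped_edge = dropped,
                 pre_samples = cfg$pre_samples,
                 post_samples = cfg$post_samples),
            class = "waveform_cluster")
}

#' @export
print.waveform_cluster <- function(x, ...) {
  cat(sprintf("<waveform_cluster> %d spikes, threshold %.3g (%d dropped at edges)\n",
              length(x$spike_times), x$threshold, x$n_dropped_edge))
  invisible(x)
}

#' Cluster signal-to-noise ratio
#'
#' `SNR = mean_i (max(s_i) - min(s_i)) / (2 * sd(eps_i))` with
#' `eps_i = s_i - s_bar` the residual of waveform `i` around the cluster
#' mean waveform; `sd` is the sample standard deviation over snippet samples.
#' Higher SNR means cleaner, more stereotyped waveforms.
#'
#' @param cluster a `waveform_cluster` (or a waveform matrix, spikes x
#'   samples) with at least 2 waveforms.
#' @return scalar SNR.
#' @export
compute_snr <- function(cluster) {
  wf <- if (inherits(cluster, "waveform_cluster")) cluster$waveforms else cluster
  wf <- as.matrix(wf)
  if (nrow(wf) < 2) stop("compute_snr: need at least 2 waveforms")
  sbar <- colMeans(wf)
  eps <- sweep(wf, 2, sbar)
  sds <- apply(eps, 1, stats::sd)
  if (all(sds == 0)) {
    stop("compute_snr: identical waveforms give a degenerate noise estimate")
  }
  rng <- apply(wf, 1, function(s) max(s) - min(s))
  mean(rng / (2 * sds))
}

#' Write detected spikes to CSV
#'
#' Columns: `time_s`, `peak_amplitude`, `polarity`.
#'
#' @param cluster a `waveform_cluster`.
#' @param path output CSV.
#' @export
write_spikes_csv <- function(cluster, path) {
  stopifnot(inherits(cluster, "waveform_cluster"))
  peak_col <- cluster$pre_samples + 1L
  amp <- if (nrow(cluster$waveforms)) cluster$waveforms[, peak_col] else numeric(0)
  utils::write.csv(data.frame(time_s = cluster$spike_times,
                              peak_amplitude = amp,
                              polarity = cluster$polarity),
                   path, row.names = FALSE)
  invisible(path)
}
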