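# Unit-level precession analysis: assign spike phases against a stimulation
# reference, build sliding-window circular tracks, and classify units with
# the three-step framework (responsiveness in enough windows, significant
# circular-linear correlation, total phase shift beyond threshold).

#' Stimulation reference
#'
#' Either an ideal sinusoid at the block frequency or an LFP-derived
#' reference (narrow band-passed recording whose analytic-signal phase is
#' used, with the waveform peak mapped to 0 deg).
#'
#' @param frequency stimulation frequency, Hz.
#' @param mode `"ideal"` or `"lfp"`.
#' @param lfp a [continuous_recording()] (required for `"lfp"` mode); its
#'   first sample is taken to lie at `block_start`.
#' @param block_start,block_end block bounds, s.
#' @param ramp stimulation ramp length excluded from phase assignment, s.
#' @return object of class `stim_reference`.
#' @export
stim_reference <- function(frequency, mode = c("ideal", "lfp"), lfp = NULL,
                           block_start = 0, block_end = Inf, ramp = 10) {
  mode <- match.arg(mode)
  stopifnot(frequency > 0, block_end > block_start, ramp >= 0)
  if (mode == "lfp" && !inherits(lfp, "continuous_recording")) {
    stop("stim_reference: lfp mode needs a continuous_recording")
  }
  structure(list(frequency = frequency, mode = mode, lfp = lfp,
                 block_start = block_start, block_end = block_end,
                 ramp = ramp),
            class = "stim_reference")
}

# analytic signal via FFT (zeroing negative frequencies)
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Assign stimulation phases to event times
#'
#' Ideal mode: `phase = 360 * frac(f * (t - block_start))` so each cycle
#' starts at the waveform peak (0 deg = stimulation peak, 180 deg = trough).
#' LFP mode: the reference trace is band-passed (2nd-order Butterworth,
#' `frequency +/- 1` Hz, zero phase), the instantaneous phase is taken from
#' the analytic signal, and the peak is mapped to 0 deg.
#'
#' @param ref a [stim_reference()].
#' @param times event times, s; must lie inside the block (ramps excluded
#'   when `exclude_ramp`).
#' @param exclude_ramp drop events during the on/off ramps instead of
#'   erroring.
#' @return a [phase_sample()]; attribute `times` carries the retained event
#'   times.
#' @export
extract_stim_phase <- function(ref, times, exclude_ramp = TRUE) {
  stopifnot(inherits(ref, "stim_reference"))
  bad <- times < ref$block_start | times > ref$block_end
  if (any(bad)) {
    stop(sprintf("extract_stim_phase: %d event times outside block [%g, %g]: %s",
                 sum(bad), ref$block_start, ref$block_end,
                 paste(utils::head(times[bad], 5), collapse = ", ")))
  }
  if (exclude_ramp && ref$ramp > 0 && is.finite(ref$block_end)) {
    keep <- times >= ref$block_start + ref$ramp &
      times <= ref$block_end - ref$ramp
    times <- times[keep]
  }
  if (ref$mode == "ideal") {
    ph <- 360 * ((ref$frequency * (times - ref$block_start)) %% 1)
  } else {
    fs <- ref$lfp$sampling_rate
    nyq <- fs / 2
    lo <- max(ref$frequency - 1, 0.1) / nyq
    hi <- min(ref$frequency + 1, nyq * 0.99) / nyq
    bf <- signal::butter(2, c(lo, hi), type = "pass")
    filt <- signal::filtfilt(bf, ref$lfp$samples)
    inst <- Arg(analytic_signal(filt))      # 0 at the waveform peak
    si <- round((times - ref$block_start) * fs) + 1
    si <- pmin(pmax(si, 1), length(filt))
    ph <- wrap_deg(rad2deg(inst[si]))
  }
  out <- phase_sample(ph, unit = "deg")
  attr(out, "times") <- times
  out
}

#' Sliding-window scheme
#'
#' @param window_length window extent (s for spike tracks, trials for MEP
#'   tracks).
#' @param step step between window starts, same units.
#' @param n_windows number of windows.
#' @param block_length optional; a warning is issued when
#'   `window_length + (n_windows - 1) * step` does not match it.
#' @return object of class `windowing_scheme`.
#' @export
windowing_scheme <- function(window_length, step, n_windows,
                             block_length = NULL) {
  stopifnot(window_length > 0, step > 0, n_windows >= 1)
  span <- window_length + (n_windows - 1) * step
  if (!is.null(block_length) && abs(span - block_length) > 1e-9) {
    warning(sprintf(
      "windowing_scheme: windows span %g but block length is %g", span,
      block_length))
  }
  structure(list(window_length = window_length, step = step,
                 n_windows = as.integer(n_windows), span = span),
            class = "windowing_scheme")
}

#' Build a windowed circular track from spike phases
#'
#' Splits phase-assigned spikes into sliding windows over time and computes a
#' circular summary (PLV, preferred phase, Rayleigh p) per window. With
#' multiple blocks, spikes are pooled across blocks at matched window index
#' (times are interpreted relative to each block start).
#'
#' @param spike_times spike times, s, relative to block start; either one
#'   numeric vector or a list of vectors (one per block).
#' @param phases matching phase vector(s), degrees.
#' @param scheme a [windowing_scheme()] in seconds.
#' @param min_spikes windows with fewer spikes are marked non-responsive.
#' @param alpha Rayleigh responsiveness level.
#' @param unit_id label carried through.
#' @return object of class `windowed_phase_track`: data frame `windows` with
#'   per-window summaries and `responsive` flags.
#' @export
window_track <- function(spike_times, phases, scheme, min_spikes = 10,
                         alpha = 0.05, unit_id = "unit") {
  if (!is.list(spike_times)) spike_times <- list(spike_times)
  if (!is.list(phases)) phases <- list(phases)
  stopifnot(length(spike_times) == length(phases))
  starts <- (seq_len(scheme$n_windows) - 1) * scheme$step
  rows <- lapply(seq_len(scheme$n_windows), function(w) {
    ph <- unlist(lapply(seq_along(spike_times), function(b) {
      tt <- spike_times[[b]]
      sel <- tt >= starts[w] & tt < starts[w] + scheme$window_length
      phases[[b]][sel]
    }))
    n <- length(ph)
    if (n >= max(min_spikes, 2)) {
      s <- circular_summary(phase_sample(ph, unit = "deg"))
      data.frame(window = w, n = n, plv = s$plv,
                 preferred_phase = s$preferred_phase,
                 phase_defined = s$phase_defined,
                 rayleigh_p = s$rayleigh_p,
                 responsive = is.finite(s$rayleigh_p) && s$rayleigh_p < alpha)
    } else {
      data.frame(window = w, n = n, plv = NA_real_,
                 preferred_phase = NA_real_, phase_defined = FALSE,
                 rayleigh_p = NA_real_, responsive = FALSE)
    }
  })
  structure(list(windows = do.call(rbind, rows), unit_id = unit_id,
                 scheme = scheme),
            class = "windowed_phase_track")
}

#' @export
print.windowed_phase_track <- function(x, ...) {
  cat(sprintf("<windowed_phase_track> %s: %d windows, %d responsive\n",
              x$unit_id, nrow(x$windows), sum(x$windows$responsive)))
  invisible(x)
}

# cumulative unwrapped phase along responsive windows, so a drift through
# 360 deg is not aliased by the last-minus-first difference
unwrap_track_phases <- function(pref) {
  if (length(pref) <= 1) return(pref)
  steps <- angular_difference(pref[-length(pref)], pref[-1])
  pref[1] + c(0, cumsum(steps))
}

#' Classify a unit's phase-shift behaviour
#'
#' Three-step framework: (1) keep units responsive (Rayleigh p < 0.05 with
#' enough spikes) in at least `max(min_windows, 50%)` of windows, else
#' `non-responsive`; (2) require a significant circular-linear correlation of
#' preferred phase against window index over the responsive windows
#' (`r > r_threshold` and `p < 0.05`); (3) require a total unwrapped phase
#' shift between the first and last responsive window beyond
#' `shift_threshold`. The sign of the shift gives the label: negative =
#' `clockwise`, positive = `counter-clockwise`. Units passing step 2 but not
#' step 3 are `stable`; units failing step 2 are `stable` when their total
#' shift is small and `non-uniform` otherwise.
#'
#' @param track a [window_track()] result.
#' @param min_windows minimum responsive-window count (default 10).
#' @param r_threshold circular-linear correlation threshold (default 0.5).
#' @param shift_threshold total-shift threshold, degrees (default 15).
#' @return object of class `precession_classification`: `label`,
#'   `total_shift` (deg), `r_circlin`, `p_circlin`, `n_responsive_windows`.
#' @export
classify_precession <- function(track, min_windows = 10, r_threshold = 0.5,
                                shift_threshold = 15) {
  stopifnot(inherits(track, "windowed_phase_track"))
  w <- track$windows
  n_windows <- nrow(w)
  resp <- which(w$responsive & w$phase_defined)
  need <- max(min_windows, ceiling(0.5 * n_windows))
  res <- list(label = NA_character_, total_shift = NA_real_,
              r_circlin = NA_real_, p_circlin = NA_real_,
              n_responsive_windows = length(resp),
              unit_id = track$unit_id)
  if (length(resp) < need) {
    res$label <- "non-responsive"
    return(structure(res, class = "precession_classification"))
  }
  pref <- w$preferred_phase[resp]
  unwrapped <- unwrap_track_phases(pref)
  res$total_shift <- unwrapped[length(unwrapped)] - unwrapped[1]
  cl <- circ_lin_corr(phase_sample(pref, unit = "deg"), resp)
  res$r_circlin <- cl$r
  res$p_circlin <- cl$p
  if (cl$r > r_threshold && cl$p < 0.05) {
    if (abs(res$total_shift) > shift_threshold) {
      res$label <- if (res$total_shift > 0) "counter-clockwise" else "clockwise"
    } else {
      res$label <- "stable"
    }
  } else {
    res$label <- if (abs(res$total_shift) <= shift_threshold) "stable" else "non-uniform"
  }
  structure(res, class = "precession_classification")
}

#' @export
print.precession_classification <- function(x, ...) {
  cat(sprintf(
    "<precession_classification> %s: %s (shift %.1f deg, r = %.2f, p = %.3g, %d responsive windows)\n",
    x$unit_id, x$label, x$total_shift, x$r_circlin, x$p_circlin,
    x$n_responsive_windows))
  invisible(x)
}

#' Summarize classifications over a unit population
#'
#' @param classifications list of [classify_precession()] results.
#' @return data frame with per-label `count` and arithmetic `mean_shift` of
#'   the signed total shifts (NA where shifts are undefined).
#' @export
summarize_population <- function(classifications) {
  if (length(classifications) == 0) stop("summarize_population: empty list")
  labels <- c("counter-clockwise", "clockwise", "stable", "non-uniform",
              "non-responsive")
  lab <- vapply(classifications, function(x) x$label, character(1))
  shift <- vapply(classifications, function(x) x$total_shift, numeric(1))
  do.call(rbind, lapply(labels, function(L) {
    sel <- lab == L
    data.frame(label = L, count = sum(sel),
               mean_shift = if (any(sel) && any(is.finite(shift[sel])))
                 mean(shift[sel], na.rm = TRUE) else NA_real_)
  }))
}

#' Compare firing rate and PLV across pre / during / post segments
#'
#' @param spike_times spike times, s (session clock).
#' @param ref a [stim_reference()] whose frequency defines the (virtual)
#'   waveform for all segments; phases are assigned with the ideal-sinusoid
#'   rule relative to each segment start.
#' @param segments data frame with columns `segment`, `start`, `end` (s);
#'   segments must not overlap.
#' @return data frame: `segment`, `n_spikes`, `rate_hz`, `plv`,
#'   `preferred_phase`, `phase_defined`.
#' @export
pre_during_post_compare <- function(spike_times, ref, segments) {
  stopifnot(all(c("segment", "start", "end") %in% names(segments)))
  o <- order(segments$start)
  segments <- segments[o, ]
  if (any(segments$start[-1] < segments$end[-nrow(segments)])) {
    stop("pre_during_post_compare: overlapping segments")
  }
  rows <- lapply(seq_len(nrow(segments)), function(i) {
    s <- segments[i, ]
    tt <- spike_times[spike_times >= s$start & spike_times < s$end]
    dur <- s$end - s$start
    if (length(tt) == 0) {
      return(data.frame(segment = s$segment, n_spikes = 0L, rate_hz = 0,
                        plv = NA_real_, preferred_phase = NA_real_,
                        phase_defined = FALSE))
    }
    seg_ref <- stim_reference(ref$frequency, "ideal", block_start = s$start,
                              block_end = s$end, ramp = 0)
    ph <- extract_stim_phase(seg_ref, tt, exclude_ramp = FALSE)
    cs <- circular_summary(ph)
    data.frame(segment = s$segment, n_spikes = length(tt),
               rate_hz = length(tt) / dur, plv = cs$plv,
               preferred_phase = cs$preferred_phase,
               phase_defined = cs$phase_defined)
  })
  do.call(rbind, rows)
}

#' Write a windowed track or classification set to tidy CSV
#'
#' @param track a `windowed_phase_track`.
#' @param path output CSV.
#' @export
write_track_csv <- function(track, path) {
  stopifnot(inherits(track, "windowed_phase_track"))
  df <- track$windows
  df$unit_id <- track$unit_id
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
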