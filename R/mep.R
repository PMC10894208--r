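# Macroscale excitability analysis: per-phase MEP aggregation, the polar
# excitability vector, sliding-window phase-drift estimation, the
# phase-independent amplitude trend, and a permutation null for drift.

MEP_PHASES <- c(0, 90, 180, 270)

#' MEP trial series
#'
#' Ordered TMS-probe trials with the AC phase at which each pulse was
#' applied and the resulting motor-evoked potential amplitude.
#'
#' @param trials data frame with columns `trial_index` (within block),
#'   `block`, `phase_deg` (one of 0/90/180/270) and `amplitude_mv` (`>= 0`).
#' @return object of class `mep_series`.
#' @export
mep_series <- function(trials) {
  need <- c("trial_index", "block", "phase_deg", "amplitude_mv")
  stopifnot(is.data.frame(trials), all(need %in% names(trials)))
  if (!all(trials$phase_deg %in% MEP_PHASES)) {
    stop("mep_series: phase_deg must be one of 0, 90, 180, 270")
  }
  if (any(trials$amplitude_mv < 0)) stop("mep_series: negative amplitudes")
  trials <- trials[order(trials$block, trials$trial_index), need]
  structure(list(trials = trials,
                 n_blocks = length(unique(trials$block))),
            class = "mep_series")
}

#' @export
print.mep_series <- function(x, ...) {
  tab <- table(x$trials$block)
  cat(sprintf("<mep_series> %d trials over %d blocks (%s per block)\n",
              nrow(x$trials), x$n_blocks,
              paste(as.integer(tab), collapse = "/")))
  invisible(x)
}

#' Read / write an MEP series as CSV
#'
#' Columns: `trial_index`, `block`, `phase_deg`, `amplitude_mv`.
#'
#' @param path CSV file.
#' @return an [mep_series()].
#' @export
read_mep_csv <- function(path) mep_series(utils::read.csv(path))

#' @rdname read_mep_csv
#' @param series an [mep_series()] to write.
#' @export
write_mep_csv <- function(series, path) {
  stopifnot(inherits(series, "mep_series"))
  utils::write.csv(series$trials, path, row.names = FALSE)
  invisible(path)
}

#' Normalize MEP amplitudes
#'
#' Divides each amplitude by the mean of its scope (block or whole session),
#' so each scope has mean 1; block scope removes between-block gain changes.
#'
#' @param series an [mep_series()].
#' @param scope `"block"` (default) or `"session"`.
#' @return a normalized [mep_series()].
#' @export
normalize_meps <- function(series, scope = c("block", "session")) {
  scope <- match.arg(scope)
  stopifnot(inherits(series, "mep_series"))
  tr <- series$trials
  if (scope == "session") {
    m <- mean(tr$amplitude_mv)
    if (m <= 0) stop("normalize_meps: zero session mean")
    tr$amplitude_mv <- tr$amplitude_mv / m
  } else {
    for (b in unique(tr$block)) {
      sel <- tr$block == b
      m <- mean(tr$amplitude_mv[sel])
      if (m <= 0) stop(sprintf("normalize_meps: zero mean in block %s", b))
      tr$amplitude_mv[sel] <- tr$amplitude_mv[sel] / m
    }
  }
  mep_series(tr)
}

#' Mean normalized amplitude per stimulation phase
#'
#' @param series an [mep_series()] (normalize first for comparability).
#' @param trials optional subset of the trial data frame (used by the
#'   sliding-window track).
#' @return data frame `phase_deg`, `mean_amplitude`, `n`; phases with no
#'   trials carry `NA` and are flagged by `n = 0`.
#' @export
phase_means <- function(series = NULL, trials = NULL) {
  if (is.null(trials)) {
    stopifnot(inherits(series, "mep_series"))
    trials <- series$trials
  }
  out <- data.frame(phase_deg = MEP_PHASES, mean_amplitude = NA_real_,
                    n = 0L)
  for (i in seq_along(MEP_PHASES)) {
    sel <- trials$phase_deg == MEP_PHASES[i]
    out$n[i] <- sum(sel)
    if (out$n[i] > 0) out$mean_amplitude[i] <- mean(trials$amplitude_mv[sel])
  }
  out
}

#' Polar excitability vector from per-phase means
#'
#' Cartesian coordinates follow the excitability-contrast convention
#' `x = M(180) - M(0)`, `y = M(270) - M(90)`; the preferred phase is the
#' amplitude-weighted circular mean of the four phase means, which under
#' this convention maps a pure `+x` vector to 180 deg and a pure `+y` vector
#' to 270 deg (`preferred = atan2(y, x) + 180`). Magnitude near 0 (uniform
#' means) leaves the phase undefined.
#'
#' @param means output of [phase_means()] (all four phases present).
#' @param tol magnitude below which the phase is flagged undefined.
#' @return object of class `polar_excitability_vector`: `x`, `y`,
#'   `magnitude`, `preferred_phase` (deg; `NA` when undefined),
#'   `phase_defined`.
#' @export
polar_vector <- function(means, tol = 1e-9) {
  stopifnot(all(MEP_PHASES %in% means$phase_deg))
  if (any(means$n == 0)) stop("polar_vector: a phase has no trials")
  M <- means$mean_amplitude[match(MEP_PHASES, means$phase_deg)]
  x <- M[3] - M[1]
  y <- M[4] - M[2]
  mag <- sqrt(x^2 + y^2)
  if (mag <= tol) {
    out <- list(x = x, y = y, magnitude = mag,
                preferred_phase = NA_real_, phase_defined = FALSE)
  } else {
    out <- list(x = x, y = y, magnitude = mag,
                preferred_phase = wrap_deg(rad2deg(atan2(y, x)) + 180),
                phase_defined = TRUE)
  }
  structure(out, class = "polar_excitability_vector")
}

#' @export
print.polar_excitability_vector <- function(x, ...) {
  cat(sprintf("<polar_excitability_vector> |v| = %.4f, preferred = %s deg\n",
              x$magnitude,
              if (x$phase_defined) sprintf("%.1f", x$preferred_phase) else "undefined"))
  invisible(x)
}

#' Sliding-window polar track of MEP phase preference
#'
#' Within each block, windows of `window` consecutive trials advance in
#' steps of `step` trials; per window and block the polar excitability
#' vector is computed from the per-phase means, then vectors are averaged
#' across blocks at matched window index (vector averaging: mean x, mean y).
#'
#' @param series an [mep_series()]; normalized per block internally.
#' @param window window length in trials (default 55).
#' @param step step in trials (default 5).
#' @param n_windows number of windows (default 20).
#' @param normalize_scope passed to [normalize_meps()].
#' @return data frame: `window`, `x`, `y`, `magnitude`, `preferred_phase`,
#'   `phase_defined`.
#' @export
windowed_polar_track <- function(series, window = 55, step = 5,
                                 n_windows = 20,
                                 normalize_scope = "block") {
  stopifnot(inherits(series, "mep_series"))
  series <- normalize_meps(series, scope = normalize_scope)
  tr <- series$trials
  blocks <- unique(tr$block)
  need <- window + (n_windows - 1) * step
  counts <- table(tr$block)
  if (any(counts < need)) {
    stop(sprintf(
      "windowed_polar_track: need >= %d trials per block (window %d + %d steps of %d); smallest block has %d",
      need, window, n_windows - 1, step, min(counts)))
  }
  xs <- matrix(NA_real_, n_windows, length(blocks))
  ys <- matrix(NA_real_, n_windows, length(blocks))
  for (bi in seq_along(blocks)) {
    btr <- tr[tr$block == blocks[bi], ]
    btr <- btr[order(btr$trial_index), ]
    for (w in seq_len(n_windows)) {
      i0 <- (w - 1) * step + 1
      sub <- btr[i0:(i0 + window - 1), ]
      pm <- phase_means(trials = sub)
      if (any(pm$n == 0)) next   # window missing a phase: leave NA
      pv <- polar_vector(pm)
      xs[w, bi] <- pv$x
      ys[w, bi] <- pv$y
    }
  }
  x <- rowMeans(xs, na.rm = TRUE)
  y <- rowMeans(ys, na.rm = TRUE)
  mag <- sqrt(x^2 + y^2)
  defined <- is.finite(mag) & mag > 1e-9
  data.frame(window = seq_len(n_windows), x = x, y = y, magnitude = mag,
             preferred_phase = ifelse(defined,
                                      wrap_deg(rad2deg(atan2(y, x)) + 180),
                                      NA_real_),
             phase_defined = defined)
}

#' Circular-linear drift correlation of a polar track
#'
#' @param track output of [windowed_polar_track()] (or a
#'   `windowed_phase_track`).
#' @return list `r`, `p`, `n` from [circ_lin_corr()] of window preferred
#'   phase against window index.
#' @export
drift_correlation <- function(track) {
  if (inherits(track, "windowed_phase_track")) track <- track$windows
  ok <- track$phase_defined & is.finite(track$preferred_phase)
  if (sum(ok) < 3) stop("drift_correlation: fewer than 3 windows with a defined phase")
  circ_lin_corr(phase_sample(track$preferred_phase[ok], unit = "deg"),
                track$window[ok])
}

#' Phase-independent amplitude trend
#'
#' Pearson correlation of block-normalized amplitude against within-block
#' trial index, pooling trials over blocks (each block contributes its own
#' index ramp, so a consistent within-block drift accumulates).
#'
#' @param series an [mep_series()].
#' @param normalize_scope passed to [normalize_meps()].
#' @return list `r`, `p`, `n`.
#' @export
amplitude_trend <- function(series, normalize_scope = "block") {
  stopifnot(inherits(series, "mep_series"))
  series <- normalize_meps(series, scope = normalize_scope)
  tr <- series$trials
  if (nrow(tr) < 3) stop("amplitude_trend: need at least 3 trials")
  if (stats::sd(tr$amplitude_mv) == 0) {
    stop("amplitude_trend: constant amplitudes")
  }
  ct <- stats::cor.test(tr$trial_index, tr$amplitude_mv)
  list(r = unname(ct$estimate), p = ct$p.value, n = nrow(tr))
}

#' Permutation null for the phase-drift correlation
#'
#' Shuffles phase labels within each block (trial order and amplitudes kept),
#' recomputes the full windowed polar track and its drift correlation each
#' time, and reports the fraction of null `r` values at or above the
#' observed `r`.
#'
#' @param series an [mep_series()].
#' @param n_perm number of permutations (`>= 100`).
#' @param seed integer seed.
#' @param window,step,n_windows passed to [windowed_polar_track()].
#' @return list `observed_r`, `null_r` (length `n_perm`), `p_perm`.
#' @export
permutation_null_drift <- function(series, n_perm = 500, seed = NULL,
                                   window = 55, step = 5, n_windows = 20) {
  stopifnot(inherits(series, "mep_series"))
  if (n_perm < 100) stop("permutation_null_drift: n_perm must be >= 100")
  if (!is.null(seed)) set.seed(seed)
  obs <- drift_correlation(
    windowed_polar_track(series, window, step, n_windows))$r
  tr <- series$trials
  null_r <- vapply(seq_len(n_perm), function(i) {
    perm <- tr
    for (b in unique(perm$block)) {
      sel <- perm$block == b
      perm$phase_deg[sel] <- sample(perm$phase_deg[sel])
    }
    tk <- windowed_polar_track(mep_series(perm), window, step, n_windows)
    out <- tryCatch(drift_correlation(tk)$r, error = function(e) NA_real_)
    out
  }, numeric(1))
  ok <- is.finite(null_r)
  list(observed_r = obs, null_r = null_r,
       p_perm = mean(null_r[ok] >= obs))
}
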