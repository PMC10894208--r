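# Seeded generators emulating the statistical structure the analyses assume:
# von Mises spike phases with optional linear phase drift, extracellular
# traces (templates + Gaussian noise + sinusoidal AC artifact), and
# phase-labelled MEP trial series. Every generator returns the ground truth
# beside the data so pipeline tests consume (data, truth) pairs only.

#' Draw from a von Mises distribution
#'
#' Best-Fisher rejection sampler. `kappa = 0` falls back to the circular
#' uniform.
#'
#' @param n number of draws.
#' @param mu mean direction, radians.
#' @param kappa concentration, `>= 0`.
#' @return radians in `[0, 2*pi)`.
#' @export
rvonmises <- function(n, mu = 0, kappa = 0) {
  stopifnot(n >= 0, kappa >= 0)
  if (n == 0L) return(numeric(0))
  if (kappa == 0) return(stats::runif(n, 0, 2 * pi))
  if (kappa < 1e-6) {
    # wrapped-uniform limit; rejection constants degenerate numerically
    return((mu + stats::runif(n, -pi, pi)) %% (2 * pi))
  }
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(0)
  while (length(out) < n) {
    m <- max(n - length(out), 16L)
    m <- ceiling(m * 1.3)
    z <- cos(pi * stats::runif(m))
    f <- (1 + r * z) / (r + z)
    c_ <- kappa * (r - f)
    u2 <- stats::runif(m)
    ok <- (c_ * (2 - c_) - u2 > 0) | (log(c_ / u2) + 1 - c_ >= 0)
    if (any(ok)) {
      u3 <- stats::runif(sum(ok))
      theta <- sign(u3 - 0.5) * acos(pmin(pmax(f[ok], -1), 1))
      out <- c(out, (mu + theta) %% (2 * pi))
    }
  }
  out[seq_len(n)]
}

#' Generate a phase-locked spike train with optional phase drift
#'
#' Homogeneous-rate spikes whose phases relative to an ideal sinusoidal
#' stimulation reference follow von Mises(mu(t), kappa) with
#' `mu(t) = mu0 + drift * t / duration`; spike rate and phase are generated
#' independently (rate-independent precession). Each spike time is placed at
#' the nearest cycle consistent with its drawn phase.
#'
#' @param duration block length, s.
#' @param rate mean firing rate, Hz.
#' @param kappa von Mises concentration (`0` = uniform phases).
#' @param mu0 initial preferred phase, degrees.
#' @param drift total linear phase drift over the block, degrees
#'   (negative = clockwise).
#' @param stim_frequency reference frequency, Hz.
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return list with `spike_times` (s, sorted), `phases_deg` (assigned truth
#'   phases) and `truth` (the generating parameters).
#' @export
gen_spike_train <- function(duration, rate, kappa, mu0 = 90, drift = 0,
                            stim_frequency = 10, seed = NULL) {
  if (rate < 0) stop("gen_spike_train: negative rate")
  stopifnot(duration > 0, kappa >= 0, stim_frequency > 0)
  if (!is.null(seed)) set.seed(seed)
  n <- stats::rpois(1, rate * duration)
  if (n == 0L) {
    return(list(spike_times = numeric(0), phases_deg = numeric(0),
                truth = list(duration = duration, rate = rate, kappa = kappa,
                             mu0 = mu0, drift = drift,
                             stim_frequency = stim_frequency)))
  }
  # nominal spike times set the drift clock; phases are then drawn around
  # mu(t) and each spike snapped to the nearest cycle realizing its phase
  t_nom <- sort(stats::runif(n, 0, duration))
  mu_t <- deg2rad(mu0 + drift * t_nom / duration)
  ph <- rvonmises(n, 0, kappa)            # deviations around mu(t)
  ph <- (mu_t + ph) %% (2 * pi)
  period <- 1 / stim_frequency
  cyc <- round((t_nom - ph / (2 * pi) * period) / period)
  times <- cyc * period + ph / (2 * pi) * period
  keep <- times >= 0 & times < duration
  o <- order(times[keep])
  list(spike_times = times[keep][o],
       phases_deg = wrap_deg(rad2deg(ph[keep][o])),
       truth = list(duration = duration, rate = rate, kappa = kappa,
                    mu0 = mu0, drift = drift,
                    stim_frequency = stim_frequency))
}

#' Default biphasic extracellular spike template
#'
#' 32-sample biphasic waveform (sharp negative trough, slower positive
#' rebound), peak normalized to 1, trough at index 9 so that the standard
#' 8-before/24-after snippet aligns on it.
#'
#' @param n_samples snippet length.
#' @param trough_index 1-based index of the extremum.
#' @return numeric template with `max(abs()) == 1`.
#' @export
spike_template <- function(n_samples = 32, trough_index = 9) {
  i <- seq_len(n_samples) - trough_index
  w <- -exp(-(i / 2.2)^2) + 0.45 * exp(-((i - 6) / 5.5)^2)
  w / max(abs(w))
}

#' Generate a continuous extracellular trace with known spike times
#'
#' Gaussian background noise + scaled spike templates at Poisson-ish
#' non-overlapping times + optional sinusoidal AC artifact.
#'
#' @param duration s.
#' @param sampling_rate Hz.
#' @param n_spikes templates to place.
#' @param template waveform (see [spike_template()]); scaled so its extremum
#'   is `amplitude_sigma * noise_sigma`.
#' @param amplitude_sigma template peak in units of noise SD.
#' @param noise_sigma background SD (trace units).
#' @param artifact_amplitude,artifact_freq optional sinusoid (same units, Hz).
#' @param min_separation minimum spacing between placed templates, s.
#' @param seed integer seed.
#' @return list: `recording` (a [continuous_recording()]), `spike_times`
#'   (truth, s, time of the template extremum), `truth` parameter echo.
#' @export
gen_extracellular_trace <- function(duration = 10, sampling_rate = 30000,
                                    n_spikes = 40,
                                    template = spike_template(),
                                    amplitude_sigma = 8, noise_sigma = 1,
                                    artifact_amplitude = 0,
                                    artifact_freq = 10,
                                    min_separation = 0.01, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- round(duration * sampling_rate)
  L <- length(template)
  if (L > n) stop("gen_extracellular_trace: template longer than trace")
  need <- n_spikes * ceiling(min_separation * sampling_rate)
  if (need > 0.8 * n) stop("gen_extracellular_trace: infeasible placement density")
  x <- stats::rnorm(n, 0, noise_sigma)
  if (artifact_amplitude > 0) {
    tt <- (seq_len(n) - 1) / sampling_rate
    x <- x + artifact_amplitude * sin(2 * pi * artifact_freq * tt)
  }
  trough <- which.max(abs(template))
  # rejection placement with a guard margin at both trace ends
  lo <- trough + 1L
  hi <- n - (L - trough) - 1L
  centers <- integer(0)
  sep <- ceiling(min_separation * sampling_rate)
  tries <- 0L
  while (length(centers) < n_spikes) {
    cand <- sample(lo:hi, 1L)
    if (all(abs(cand - centers) >= sep)) centers <- c(centers, cand)
    tries <- tries + 1L
    if (tries > 10000L * n_spikes) {
      stop("gen_extracellular_trace: infeasible placement density")
    }
  }
  centers <- sort(centers)
  amp <- amplitude_sigma * noise_sigma
  for (c0 in centers) {
    idx <- (c0 - trough + 1L):(c0 - trough + L)
    x[idx] <- x[idx] + amp * template
  }
  list(recording = continuous_recording(x, sampling_rate, "synthetic"),
       spike_times = (centers - 1) / sampling_rate,
       truth = list(duration = duration, sampling_rate = sampling_rate,
                    n_spikes = n_spikes, amplitude_sigma = amplitude_sigma,
                    noise_sigma = noise_sigma,
                    artifact_amplitude = artifact_amplitude,
                    artifact_freq = artifact_freq))
}

#' Generate a phase-labelled MEP trial series
#'
#' Emulates the macroscale TMS-probe design: trials cycle over the four
#' probed phases {0, 90, 180, 270} deg; amplitudes carry a cosine phase
#' tuning whose preferred phase drifts linearly within each block from
#' `mu_start` to `mu_end`, multiplicative lognormal noise, and an optional
#' within-block linear amplitude trend.
#'
#' `amplitude = base * (1 + depth * cos(phase - mu(t))) * lognormal(cv) *
#'  (1 + trend_slope * frac_block)`.
#'
#' @param n_blocks,trials_per_block design size (default 4 x 150).
#' @param modulation_depth fractional tuning depth in `[0, 1)`.
#' @param mu_start,mu_end preferred phase at block start / end, degrees.
#' @param amplitude_cv coefficient of variation of the lognormal noise.
#' @param trend_slope fractional amplitude gain over one block.
#' @param base_amplitude mean MEP size, mV.
#' @param seed integer seed.
#' @return list: `series` (an [mep_series()]) and `truth`.
#' @export
gen_mep_series <- function(n_blocks = 4, trials_per_block = 150,
                           modulation_depth = 0.07,
                           mu_start = 90, mu_end = 180,
                           amplitude_cv = 0.3, trend_slope = 0,
                           base_amplitude = 1, seed = NULL) {
  if (modulation_depth >= 1 || modulation_depth < 0) {
    stop("gen_mep_series: modulation_depth must be in [0, 1)")
  }
  stopifnot(n_blocks >= 1, trials_per_block >= 4)
  if (!is.null(seed)) set.seed(seed)
  labels <- c(0, 90, 180, 270)
  rows <- vector("list", n_blocks)
  sdlog <- sqrt(log(1 + amplitude_cv^2))
  for (b in seq_len(n_blocks)) {
    idx <- seq_len(trials_per_block)
    frac <- (idx - 1) / (trials_per_block - 1)
    mu <- mu_start + (mu_end - mu_start) * frac
    ph <- sample(rep(labels, length.out = trials_per_block))
    tuning <- 1 + modulation_depth * cos(deg2rad(ph - mu))
    noise <- stats::rlnorm(trials_per_block, -sdlog^2 / 2, sdlog)
    amp <- base_amplitude * tuning * noise * (1 + trend_slope * frac)
    rows[[b]] <- data.frame(trial_index = idx, block = b,
                            phase_deg = ph, amplitude_mv = amp)
  }
  df <- do.call(rbind, rows)
  list(series = mep_series(df),
       truth = list(n_blocks = n_blocks, trials_per_block = trials_per_block,
                    modulation_depth = modulation_depth, mu_start = mu_start,
                    mu_end = mu_end, amplitude_cv = amplitude_cv,
                    trend_slope = trend_slope,
                    base_amplitude = base_amplitude))
}
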