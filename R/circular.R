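# Circular statistics shared by the unit-level, MEP-level and model-level
# pipelines. Convention, package-wide: 0 deg = stimulation peak, 180 deg =
# stimulation trough; angles increase counter-clockwise. Interfaces take and
# return degrees; internals work in radians.

deg2rad <- function(deg) deg * pi / 180
rad2deg <- function(rad) rad * 180 / pi

#' Wrap angles into a canonical interval
#'
#' @param deg numeric vector of angles in degrees.
#' @return angles wrapped to `[0, 360)`.
#' @export
wrap_deg <- function(deg) {
  out <- deg %% 360
  out[out == 360] <- 0
  out
}

#' Phase sample container
#'
#' Bundles event phases (spike phases, MEP-probe phases, ...) relative to an
#' oscillation. Phases are stored in radians wrapped to `[0, 2*pi)`.
#'
#' @param phases numeric vector of angles.
#' @param unit `"deg"` or `"rad"` for the input; storage is always radians.
#' @return an object of class `phase_sample` with elements `phases` (radians)
#'   and `n`.
#' @export
phase_sample <- function(phases, unit = c("deg", "rad")) {
  unit <- match.arg(unit)
  if (is.null(phases)) phases <- numeric(0)
  stopifnot(is.numeric(phases))
  if (anyNA(phases)) stop("phase_sample: phases contain NA")
  rad <- if (unit == "deg") deg2rad(phases) else phases
  rad <- rad %% (2 * pi)
  rad[rad == 2 * pi] <- 0
  structure(list(phases = as.numeric(rad), n = length(rad)),
            class = "phase_sample")
}

as_phase_sample <- function(x, unit = "rad") {
  if (inherits(x, "phase_sample")) x else phase_sample(x, unit = unit)
}

#' @export
print.phase_sample <- function(x, ...) {
  cat(sprintf("<phase_sample> n = %d events\n", x$n))
  invisible(x)
}

resultant <- function(sample) {
  # complex mean vector; the workhorse behind PLV / circular mean / Rayleigh
  if (sample$n == 0L) stop("empty phase sample: no events")
  mean(exp(1i * sample$phases))
}

#' Phase-locking value
#'
#' Magnitude of the mean unit phase vector over events,
#' `PLV = |sum(exp(i * theta_k))| / N`. 0 means no synchronization between
#' spikes and the oscillation, 1 means perfect synchronization.
#'
#' @param sample a [phase_sample()] (or numeric radians).
#' @return scalar in `[0, 1]`.
#' @export
compute_plv <- function(sample) {
  sample <- as_phase_sample(sample)
  if (sample$n == 0L) stop("compute_plv: empty phase sample (no events)")
  min(Mod(resultant(sample)), 1)
}

#' Circular (resultant-vector) mean phase
#'
#' Preferred phase: argument of the resultant vector, in degrees. Undefined
#' (zero resultant, e.g. antipodal or uniform phases) is reported as an
#' explicit `NA` with attribute `defined = FALSE`, never as a silent 0.
#'
#' @param sample a [phase_sample()].
#' @param tol resultant lengths below `tol` count as undefined.
#' @return preferred phase in degrees `[0, 360)`, or `NA` (attr `defined`).
#' @export
circular_mean <- function(sample, tol = 1e-9) {
  sample <- as_phase_sample(sample)
  if (sample$n == 0L) stop("circular_mean: empty phase sample")
  z <- resultant(sample)
  if (Mod(z) <= tol) {
    return(structure(NA_real_, defined = FALSE))
  }
  structure(wrap_deg(rad2deg(Arg(z))), defined = TRUE)
}

#' Rayleigh test of circular non-uniformity
#'
#' Tests the null of a uniform phase distribution against unimodal clustering,
#' via the resultant length R. Uses `Z = n * R^2` with the standard
#' small-sample corrected tail
#' `p = exp(sqrt(1 + 4 n + 4 (n^2 - Rn^2)) - (1 + 2 n))`, `Rn = n * R`.
#'
#' @param sample a [phase_sample()] with at least 2 events.
#' @return list with `p`, `z` (Rayleigh statistic) and `n`.
#' @export
rayleigh_test <- function(sample) {
  sample <- as_phase_sample(sample)
  n <- sample$n
  if (n < 2L) stop("rayleigh_test: need at least 2 events")
  R <- compute_plv(sample)
  Rn <- n * R
  z <- n * R^2
  p <- exp(sqrt(1 + 4 * n + 4 * (n^2 - Rn^2)) - (1 + 2 * n))
  p <- min(max(p, .Machine$double.xmin), 1)
  list(p = p, z = z, n = n)
}

#' Circular-linear correlation
#'
#' Correlation between a circular variable (phases) and a linear covariate,
#' composed from the three Pearson correlations
#' `r_cx = cor(cos theta, x)`, `r_sx = cor(sin theta, x)`,
#' `r_cs = cor(cos theta, sin theta)`:
#' `r = sqrt((r_cx^2 + r_sx^2 - 2 r_cx r_sx r_cs) / (1 - r_cs^2))`,
#' with p from a chi-square(2) tail on `n * r^2`.
#'
#' @param phases a [phase_sample()] or numeric radians.
#' @param covariate numeric vector, same length, not constant.
#' @return list with `r` in `[0, 1]`, `p`, `n`.
#' @export
circ_lin_corr <- function(phases, covariate) {
  phases <- as_phase_sample(phases)
  x <- as.numeric(covariate)
  n <- phases$n
  if (n != length(x)) stop("circ_lin_corr: lengths differ")
  if (n < 3L) stop("circ_lin_corr: need at least 3 pairs")
  if (stats::sd(x) == 0) stop("circ_lin_corr: constant covariate is degenerate")
  ct <- cos(phases$phases)
  st <- sin(phases$phases)
  if (stats::sd(ct) == 0 && stats::sd(st) == 0) {
    stop("circ_lin_corr: constant phase is degenerate")
  }
  # a phase sample constant in one coordinate only (all cos equal, sin
  # varying or vice versa) degrades to a single Pearson correlation
  if (stats::sd(ct) == 0) {
    r <- abs(stats::cor(st, x))
  } else if (stats::sd(st) == 0) {
    r <- abs(stats::cor(ct, x))
  } else {
    rcx <- stats::cor(ct, x)
    rsx <- stats::cor(st, x)
    rcs <- stats::cor(ct, st)
    r2 <- (rcx^2 + rsx^2 - 2 * rcx * rsx * rcs) / (1 - rcs^2)
    r <- sqrt(max(min(r2, 1), 0))
  }
  p <- stats::pchisq(n * r^2, df = 2, lower.tail = FALSE)
  list(r = r, p = p, n = n)
}

#' Signed minimal angular difference
#'
#' Minimal signed rotation carrying angle `a` onto angle `b`, in degrees in
#' `(-180, 180]`. Positive = counter-clockwise (increasing phase); the 180
#' degree tie breaks positive.
#'
#' @param a,b angles in degrees (vectorized).
#' @return signed degrees in `(-180, 180]`.
#' @export
angular_difference <- function(a, b) {
  d <- (b - a) %% 360
  ifelse(d > 180, d - 360, d)
}

#' Circular summary of a phase sample
#'
#' PLV, preferred phase and Rayleigh p in one record; the per-window unit of
#' every sliding-window track in the package.
#'
#' @param sample a [phase_sample()].
#' @return object of class `circular_summary`: list with `plv`,
#'   `preferred_phase` (deg, `NA` when undefined), `phase_defined`,
#'   `rayleigh_p` (`NA` when n < 2) and `n`.
#' @export
circular_summary <- function(sample) {
  sample <- as_phase_sample(sample)
  if (sample$n == 0L) {
    out <- list(plv = NA_real_, preferred_phase = NA_real_,
                phase_defined = FALSE, rayleigh_p = NA_real_, n = 0L)
  } else {
    plv <- compute_plv(sample)
    mu <- circular_mean(sample)
    out <- list(
      plv = plv,
      preferred_phase = as.numeric(mu),
      phase_defined = isTRUE(attr(mu, "defined")),
      rayleigh_p = if (sample$n >= 2L) rayleigh_test(sample)$p else NA_real_,
      n = sample$n
    )
  }
  structure(out, class = "circular_summary")
}

#' @export
print.circular_summary <- function(x, ...) {
  cat(sprintf(
    "<circular_summary> n = %d, PLV = %.3f, preferred = %s deg, Rayleigh p = %s\n",
    x$n, x$plv,
    if (x$phase_defined) sprintf("%.1f", x$preferred_phase) else "undefined",
    format.pval(x$rayleigh_p, digits = 3)))
  invisible(x)
}

#' Read a phase sample from a one-column CSV of degrees
#'
#' @param path CSV file with a single column of phases in degrees.
#' @return a [phase_sample()].
#' @export
read_phase_sample_csv <- function(path) {
  df <- utils::read.csv(path)
  phase_sample(df[[1]], unit = "deg")
}

#' Write a phase sample to a one-column CSV of degrees
#'
#' @param sample a [phase_sample()].
#' @param path output file.
#' @export
write_phase_sample_csv <- function(sample, path) {
  sample <- as_phase_sample(sample)
  utils::write.csv(data.frame(phase_deg = wrap_deg(rad2deg(sample$phases))),
                   path, row.names = FALSE)
  invisible(path)
}

#' Serialize a circular summary to JSON
#'
#' Keys: `plv`, `preferred_phase_deg`, `rayleigh_p`, `n`.
#'
#' @param x a `circular_summary`.
#' @param path optional file; when `NULL` the JSON string is returned.
#' @export
circular_summary_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "circular_summary"))
  obj <- list(plv = x$plv, preferred_phase_deg = x$preferred_phase,
              rayleigh_p = x$rayleigh_p, n = x$n)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, na = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}
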