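# Unit-level pipeline: phase assignment, sliding-window tracks, and the
# three-step precession classification framework.

make_track <- function(duration = 360, rate = 1.5, kappa = 3, mu0 = 90,
                       drift = 0, seed = 1, n_blocks = 1, min_spikes = 10) {
  spikes <- list(); phases <- list()
  for (b in seq_len(n_blocks)) {
    g <- gen_spike_train(duration, rate, kappa, mu0, drift,
                         stim_frequency = 10, seed = seed + 1000 * (b - 1))
    spikes[[b]] <- g$spike_times
    phases[[b]] <- g$phases_deg
  }
  window_track(spikes, phases, windowing_scheme(132, 12, 20, duration),
               min_spikes = min_spikes)
}

test_that("ideal-mode phase assignment follows the block clock", {
  ref <- stim_reference(10, "ideal", block_start = 100, block_end = 500,
                        ramp = 0)
  ph <- extract_stim_phase(ref, c(100.05, 100.1, 100.125))
  expect_equal(angular_difference(wrap_deg(rad2deg(ph$phases)),
                                  c(180, 0, 90)),
               c(0, 0, 0), tolerance = 1e-6)
  ref20 <- stim_reference(20, "ideal", block_start = 0, block_end = 10,
                          ramp = 0)
  expect_equal(wrap_deg(rad2deg(extract_stim_phase(ref20, 0.025)$phases)),
               180, tolerance = 1e-9)
  expect_error(extract_stim_phase(ref, 600), "outside block")
  # ramps excluded rather than erroring
  refr <- stim_reference(10, "ideal", block_start = 0, block_end = 100,
                         ramp = 10)
  ph2 <- extract_stim_phase(refr, c(5, 50, 96))
  expect_equal(ph2$n, 1L)
})

test_that("LFP-derived phases agree with the ideal sinusoid on a clean tone", {
  fs <- 1000
  tt <- seq(0, 60 - 1 / fs, by = 1 / fs)
  lfp <- continuous_recording(cos(2 * pi * 10 * tt), fs)
  ref <- stim_reference(10, "lfp", lfp = lfp, block_start = 0,
                        block_end = 60, ramp = 0)
  times <- seq(5, 55, by = 0.093)
  ph <- wrap_deg(rad2deg(extract_stim_phase(ref, times)$phases))
  truth <- wrap_deg(360 * ((10 * times) %% 1))
  err <- abs(angular_difference(truth, ph))
  expect_lt(stats::median(err), 1)
})

test_that("windowing produces the canonical 20-window layout", {
  expect_warning(windowing_scheme(132, 12, 20, 350), "span")
  sch <- windowing_scheme(132, 12, 20, 360)
  expect_equal(sch$n_windows, 20L)
  expect_equal(sch$span, 360)
  tr <- make_track(seed = 2)
  expect_equal(nrow(tr$windows), 20)
})

test_that("stationary locked spikes give a flat responsive track", {
  tr <- make_track(kappa = 2, mu0 = 90, drift = 0, seed = 3)
  expect_true(all(tr$windows$responsive))
  dev <- abs(angular_difference(tr$windows$preferred_phase, 90))
  expect_true(all(dev <= 10))
})

test_that("empty and sparse spike trains yield non-responsive windows", {
  tr <- window_track(numeric(0), numeric(0),
                     windowing_scheme(132, 12, 20, 360))
  expect_true(all(!tr$windows$responsive))
  cl <- classify_precession(tr)
  expect_equal(cl$label, "non-responsive")
})

test_that("classification recovers planted drift direction and magnitude", {
  tr <- make_track(kappa = 4, drift = 30, seed = 4)
  cl <- classify_precession(tr)
  expect_equal(cl$label, "counter-clockwise")
  expect_gt(cl$total_shift, 15)
  expect_lt(abs(cl$total_shift - 30), 15)
  tr2 <- make_track(kappa = 4, drift = -45, seed = 5)
  expect_equal(classify_precession(tr2)$label, "clockwise")
})

test_that("small drifts fall below the 15-degree shift threshold", {
  labs <- vapply(1:10, function(sd) {
    classify_precession(make_track(kappa = 6, drift = 8, seed = 100 + sd))$label
  }, character(1))
  expect_false(any(labs %in% c("clockwise", "counter-clockwise")) &&
                 mean(labs == "stable") < 0.5)
  expect_gte(mean(labs == "stable"), 0.7)
})

test_that("responsiveness gate uses max(min_windows, half the windows)", {
  g <- gen_spike_train(360, 1.5, 3, 90, 0, 10, seed = 6)
  keep <- g$spike_times < 60   # spikes only early: few responsive windows
  tr <- window_track(g$spike_times[keep], g$phases_deg[keep],
                     windowing_scheme(132, 12, 20, 360))
  expect_lt(sum(tr$windows$responsive), 10)
  expect_equal(classify_precession(tr)$label, "non-responsive")
})

test_that("direction recovery holds across 200 planted-drift fixtures", {
  set.seed(7)
  # the track measures drift between the first and last window centers
  # (228 s of the 360 s block); plant the target drift across that span
  coverage <- (20 - 1) * 12 / 360
  drifts <- runif(200, 20, 60) * sample(c(-1, 1), 200, replace = TRUE)
  ok <- vapply(seq_along(drifts), function(i) {
    cl <- classify_precession(make_track(kappa = 2.5,
                                         drift = drifts[i] / coverage,
                                         seed = 2000 + i, n_blocks = 4))
    (cl$label == "counter-clockwise" && drifts[i] > 0) ||
      (cl$label == "clockwise" && drifts[i] < 0)
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("stationary fixtures rarely earn a precessing label", {
  labs <- vapply(1:200, function(i) {
    classify_precession(make_track(kappa = 2.5, drift = 0,
                                   seed = 4000 + i))$label
  }, character(1))
  expect_lte(mean(labs %in% c("clockwise", "counter-clockwise")), 0.10)
})

test_that("raising the shift threshold never adds precessing labels", {
  set.seed(8)
  tracks <- lapply(1:30, function(i) {
    make_track(kappa = 2.5, drift = runif(1, -40, 40), seed = 6000 + i)
  })
  counts <- vapply(c(5, 15, 30, 60), function(th) {
    sum(vapply(tracks, function(tr) {
      classify_precession(tr, shift_threshold = th)$label %in%
        c("clockwise", "counter-clockwise")
    }, logical(1)))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("pooling four identical blocks reproduces the one-block track", {
  g <- gen_spike_train(360, 2, 3, 120, 25, 10, seed = 9)
  one <- window_track(g$spike_times, g$phases_deg,
                      windowing_scheme(132, 12, 20, 360))
  four <- window_track(rep(list(g$spike_times), 4),
                       rep(list(g$phases_deg), 4),
                       windowing_scheme(132, 12, 20, 360))
  expect_equal(four$windows$preferred_phase, one$windows$preferred_phase,
               tolerance = 1e-9)
  expect_equal(four$windows$plv, one$windows$plv, tolerance = 1e-9)
})

test_that("population summary counts labels and averages signed shifts", {
  mk <- function(label, shift) {
    structure(list(label = label, total_shift = shift, r_circlin = 0.9,
                   p_circlin = 0.01, n_responsive_windows = 20,
                   unit_id = "u"), class = "precession_classification")
  }
  tab <- summarize_population(list(mk("clockwise", -20), mk("clockwise", -30),
                                   mk("clockwise", -40),
                                   mk("non-responsive", NA)))
  expect_equal(tab$count[tab$label == "clockwise"], 3)
  expect_equal(tab$mean_shift[tab$label == "clockwise"], -30)
  expect_equal(tab$count[tab$label == "counter-clockwise"], 0)
  expect_error(summarize_population(list()), "empty")
})

test_that("pre/during/post comparison sees entrainment without rate change", {
  set.seed(10)
  segs <- data.frame(segment = c("pre", "during", "post"),
                     start = c(0, 180, 540), end = c(180, 540, 720))
  pre <- gen_spike_train(180, 3, 0, 0, 0, 10, seed = 11)$spike_times
  dur <- gen_spike_train(360, 3, 1.5, 90, 0, 10, seed = 12)$spike_times + 180
  post <- gen_spike_train(180, 3, 0, 0, 0, 10, seed = 13)$spike_times + 540
  ref <- stim_reference(10, "ideal", block_start = 0, block_end = 720,
                        ramp = 0)
  tab <- pre_during_post_compare(c(pre, dur, post), ref, segs)
  expect_gt(tab$plv[tab$segment == "during"], tab$plv[tab$segment == "pre"])
  expect_gt(tab$plv[tab$segment == "during"], tab$plv[tab$segment == "post"])
  expect_lt(abs(tab$rate_hz[2] - tab$rate_hz[1]) / tab$rate_hz[1], 0.25)
  # overlapping segments rejected; empty segment reported as silent
  expect_error(pre_during_post_compare(
    1:10, ref, data.frame(segment = c("a", "b"), start = c(0, 5),
                          end = c(6, 10))), "overlap")
  tab2 <- pre_during_post_compare(c(0.5, 1.5), ref,
                                  data.frame(segment = c("a", "b"),
                                             start = c(0, 2), end = c(2, 4)))
  expect_equal(tab2$rate_hz[2], 0)
  expect_false(tab2$phase_defined[2])
})
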