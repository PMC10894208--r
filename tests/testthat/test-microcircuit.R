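# Two-compartment microcircuit: determinism, passive-limit physics against
# the closed-form RC response, field-coupling geometry, excitability, and
# the integrator's step-size robustness.

passive_config <- function(duration_stim_s = 3, seed = 1) {
  cfg <- build_default_circuit("alpha", duration_baseline_s = 1,
                               duration_stim_s = duration_stim_s, seed = seed)
  for (nm in names(cfg$neurons)) {
    cfg$neurons[[nm]]$soma$conduct[c("gNa", "gKv", "gKm", "gCa", "gKCa")] <-
      list(0, 0, 0, 0, 0)
  }
  cfg$poisson$w_uS[] <- 0
  cfg$synapses$w[] <- 0
  cfg
}

# closed-form sinusoidal steady state of the passive two-compartment pair
rc_polarization <- function(cfg, neuron, amp_vm, freq_hz) {
  nr <- cfg$neurons[[neuron]]
  uS <- function(mScm2, area) mScm2 * area * 1e3
  gls <- uS(nr$soma$conduct$gL, nr$soma$area_cm2)
  gld <- uS(nr$dend$conduct$gL, nr$dend$area_cm2)
  gc <- nr$g_c_uS
  w <- 2 * pi * freq_hz / 1000
  S <- amp_vm * nr$dend$length_um * 1e-3
  A <- matrix(c(1i * w * nr$soma$C_nF + gls + gc, -gc,
                -gc, 1i * w * nr$dend$C_nF + gld + gc), 2, 2, byrow = TRUE)
  solve(A, c(gc * S, -gc * S))
}

test_that("identical config and seed reproduce identical spike trains", {
  cfg <- build_default_circuit("alpha", duration_baseline_s = 5,
                               duration_stim_s = 5, seed = 3)
  f <- field_spec(3, 10, ramp_s = 1)
  r1 <- simulate_circuit(cfg, f)
  r2 <- simulate_circuit(cfg, f)
  expect_identical(r1$spike_times, r2$spike_times)
  r3 <- simulate_circuit(build_default_circuit("alpha",
                                               duration_baseline_s = 5,
                                               duration_stim_s = 5,
                                               seed = 4), f)
  expect_false(identical(r1$spike_times$BA6_PY, r3$spike_times$BA6_PY))
})

test_that("a drive-free network is silent and rests at the leak potential", {
  cfg <- build_default_circuit("alpha", duration_baseline_s = 2,
                               duration_stim_s = 0, seed = 1)
  cfg$poisson$w_uS[] <- 0
  res <- simulate_circuit(cfg, record_voltage_ms = 5)
  expect_true(all(vapply(res$spike_times, length, integer(1)) == 0))
  # rest sits near the leak potential (gate leak shifts it slightly) and
  # is stationary by the end of the settling period
  v_end <- vapply(res$voltages$soma, function(v) v[length(v)], numeric(1))
  expect_true(all(abs(v_end - (-70)) < 5))
  drift <- vapply(res$voltages$soma, function(v) {
    abs(v[length(v)] - v[length(v) - 20])
  }, numeric(1))
  expect_true(all(drift < 0.01))
})

test_that("passive field response matches the closed-form RC solution", {
  cfg <- passive_config()
  f <- field_spec(3, 10, ramp_s = 0.25)
  res <- simulate_circuit(cfg, f, record_voltage_ms = 0.5)
  sel <- res$voltages$t_s > 3 & res$voltages$t_s < 4
  for (nm in c("BA6_PY", "BA4_PY")) {
    vs <- res$voltages$soma[[nm]][sel]
    sim_amp <- (max(vs) - min(vs)) / 2
    ref <- Mod(rc_polarization(cfg, nm, 3, 10)[1])
    expect_lt(abs(sim_amp - ref) / ref, 0.05)
  }
})

test_that("passive polarization is linear in field amplitude", {
  cfg <- passive_config()
  amp_at <- function(a) {
    res <- simulate_circuit(cfg, field_spec(a, 10, ramp_s = 0.25),
                            record_voltage_ms = 0.5)
    sel <- res$voltages$t_s > 3 & res$voltages$t_s < 4
    vs <- res$voltages$soma$BA4_PY[sel]
    (max(vs) - min(vs)) / 2
  }
  expect_lt(abs(amp_at(2) / amp_at(1) - 2), 0.01 * 2)
})

test_that("field coupling follows the uniform-field dot-product geometry", {
  cfg <- build_default_circuit("alpha", duration_baseline_s = 0,
                               duration_stim_s = 10, seed = 1)
  # 3 V/m along the 500 um axis: 1.5 mV extracellular difference at the peak
  f <- field_spec(3, 10, t_on_s = 0, t_off_s = 10, ramp_s = 0)
  ve <- apply_extracellular_field(cfg, f, t_s = c(0, 0.025, 0.05))
  ba6 <- ve[ve$neuron == "BA6_PY", ]
  ba4 <- ve[ve$neuron == "BA4_PY", ]
  expect_equal(ba6$delta_ve_mv[1], -1.5, tolerance = 1e-9)
  expect_equal(ba4$delta_ve_mv[1], 1.5, tolerance = 1e-9)
  # anti-parallel axes: opposite polarization at every instant
  expect_equal(ba6$delta_ve_mv, -ba4$delta_ve_mv, tolerance = 1e-12)
  # perpendicular field produces no compartmental difference
  fperp <- field_spec(3, 10, direction = c(0, 1, 0), t_on_s = 0,
                      t_off_s = 10, ramp_s = 0)
  vperp <- apply_extracellular_field(cfg, fperp, t_s = 0.1)
  expect_true(all(abs(vperp$delta_ve_mv) < 1e-12))
})

test_that("a perpendicular field leaves the passive membrane unpolarized", {
  cfg <- passive_config()
  res <- simulate_circuit(cfg, field_spec(3, 10, direction = c(0, 0, 1),
                                          ramp_s = 0.25),
                          record_voltage_ms = 1)
  sel <- res$voltages$t_s > 2
  swing <- max(res$voltages$soma$BA4_PY[sel]) -
    min(res$voltages$soma$BA4_PY[sel])
  expect_lt(swing, 1e-6)
})

test_that("somatic current injection drives monotone f-I spiking", {
  rates <- vapply(c(0.1, 0.2, 0.4), function(I) {
    cfg <- build_default_circuit("alpha", duration_baseline_s = 5,
                                 duration_stim_s = 0, seed = 1)
    cfg$poisson$w_uS[] <- 0
    cfg$synapses$w[] <- 0
    cfg$neurons$BA6_PY$I_inj_nA <- I
    res <- simulate_circuit(cfg)
    length(res$spike_times$BA6_PY) / res$duration_s
  }, numeric(1))
  expect_gt(rates[1], 0)
  expect_true(all(diff(rates) > 0))
})

test_that("halving the time step changes spike counts by under 2%", {
  counts <- vapply(c(0.025, 0.0125), function(dt) {
    cfg <- build_default_circuit("alpha", dt_ms = dt,
                                 duration_baseline_s = 30,
                                 duration_stim_s = 0, seed = 5)
    sum(vapply(simulate_circuit(cfg)$spike_times, length, integer(1)))
  }, numeric(1))
  expect_lt(abs(counts[2] - counts[1]) / counts[1], 0.02)
})

test_that("sweeps validate their increments and respect a zero increment", {
  cfg <- build_default_circuit("alpha", duration_baseline_s = 1,
                               duration_stim_s = 2, seed = 1)
  f <- field_spec(3, 10, ramp_s = 0.2)
  expect_error(nmda_weight_sweep(cfg, f, n_trials = 3, increment = -0.6),
               "negative")
  sw <- nmda_weight_sweep(cfg, f, n_trials = 3, increment = 0,
                          reseed_trials = FALSE)
  expect_equal(sw$weight_uS, rep(sw$weight_uS[1], 3))
  expect_equal(sw$n_spikes, rep(sw$n_spikes[1], 3))
})

test_that("spike output serializes to a tidy CSV", {
  cfg <- build_default_circuit("alpha", duration_baseline_s = 3,
                               duration_stim_s = 0, seed = 1)
  res <- simulate_circuit(cfg)
  f <- withr::local_tempfile(fileext = ".csv")
  write_circuit_spikes_csv(res, f)
  df <- read.csv(f)
  expect_named(df, c("neuron", "time_s"))
  expect_equal(nrow(df), sum(vapply(res$spike_times, length, integer(1))))
  expect_true(all(df$time_s >= 0 & df$time_s <= 3))
})
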