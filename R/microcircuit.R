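# Three-neuron cortical microcircuit: a premotor pyramidal cell (BA6-PY)
# with its somatodendritic axis anti-parallel to a primary-motor pyramidal
# cell (BA4-PY) and a fast-spiking interneuron (IN), coupled by
# AMPA/NMDA/GABA_A dual-exponential synapses, driven by Poisson background
# input, and polarized by a uniform sinusoidal extracellular field.
# All constants here are package defaults, fully exposed in the config.

CIRCUIT_NEURONS <- c("BA6_PY", "BA4_PY", "IN")

# cylinder lateral surface, cm^2
.cyl_area_cm2 <- function(length_um, diam_um) {
  pi * diam_um * length_um * 1e-8
}

.compartment_spec <- function(length_um, diam_um, cm_uF_cm2 = 1,
                              conduct_mS_cm2 = list()) {
  area <- .cyl_area_cm2(length_um, diam_um)
  list(length_um = length_um, diam_um = diam_um, cm = cm_uF_cm2,
       area_cm2 = area, C_nF = cm_uF_cm2 * area * 1e3,
       conduct = conduct_mS_cm2)
}

.neuron_spec <- function(type = c("PY", "IN"), soma, dend, g_c_uS,
                         axis = c(1, 0, 0), EL = -70, VT = -63,
                         I_inj_nA = 0) {
  type <- match.arg(type)
  list(type = type, soma = soma, dend = dend, g_c_uS = g_c_uS,
       axis = axis / sqrt(sum(axis^2)), EL = EL, VT = VT,
       I_inj_nA = I_inj_nA)
}

.syn_row <- function(pre, post, receptor, w, delay,
                     target = c("dendrite", "soma")) {
  target <- match.arg(target)
  pars <- switch(receptor,
                 AMPA  = list(E = 0,   tau1 = 0.5, tau2 = 3,  nmda = 0L),
                 NMDA  = list(E = 0,   tau1 = 8,   tau2 = 65, nmda = 1L),
                 GABA_A = list(E = -80, tau1 = 0.5, tau2 = 8,  nmda = 0L),
                 stop("unknown receptor"))
  if ((receptor == "GABA_A") != (target == "soma")) {
    stop("excitatory synapses target the dendrite, inhibitory the soma")
  }
  data.frame(pre = pre, post = post, receptor = receptor,
             post_comp = if (target == "soma") 0L else 1L,
             is_nmda = pars$nmda, E = pars$E, tau1 = pars$tau1,
             tau2 = pars$tau2, w = w, delay = delay,
             stringsAsFactors = FALSE)
}

#' Build the default three-neuron microcircuit configuration
#'
#' Returns the fully parameterized circuit for a stimulation condition.
#' Connectivity: BA6-PY excites BA4-PY and IN (AMPA + NMDA, 2 ms delay,
#' the premotor-to-motor projection); BA4-PY excites IN and IN inhibits
#' BA4-PY (GABA_A) through a local reciprocal loop with a 1 ms delay.
#' Excitatory synapses contact the dendrite, the inhibitory synapse the
#' soma. Poisson background input (E = 0 mV, rise 2 ms, decay 10 ms) is
#' tuned so baseline pyramidal rates sit near 10 spikes/s (alpha condition)
#' or near 17 spikes/s (beta condition); in the beta condition the
#' BA6-to-IN NMDA weight is reduced to keep the interneuron rate consistent
#' across conditions. BA6-PY's somatodendritic axis is anti-parallel to
#' BA4-PY's and the IN's, so the two pyramidal cells are polarized with
#' opposite sign at every instant of the field.
#'
#' @param condition `"alpha"` (10 Hz) or `"beta"` (20 Hz).
#' @param dt_ms integration step, ms.
#' @param duration_baseline_s,duration_stim_s spans without / with field, s.
#' @param seed integer master seed for the Poisson generators.
#' @param shared_poisson all neurons share one Poisson realization when
#'   `TRUE` (default `FALSE`: independent streams off one master seed).
#' @return object of class `circuit_config`.
#' @export
build_default_circuit <- function(condition = c("alpha", "beta"),
                                  dt_ms = 0.025,
                                  duration_baseline_s = 360,
                                  duration_stim_s = 360,
                                  seed = 1, shared_poisson = FALSE) {
  condition <- match.arg(condition)
  py_soma <- .compartment_spec(20, 20, 1,
                               list(gNa = 50, gKv = 10, gKm = 0.5, gL = 0.05,
                                    gCa = 0.3, gKCa = 3))
  py_dend <- .compartment_spec(500, 5, 1, list(gL = 0.05))
  in_soma <- .compartment_spec(15, 15, 1,
                               list(gNa = 50, gKv = 10, gKm = 0, gL = 0.1,
                                    gCa = 0, gKCa = 0))
  in_dend <- .compartment_spec(300, 3, 1, list(gL = 0.1))
  # field convention: direction +x; at phase 0 (field peak) the BA4 soma is
  # depolarized, so the BA4/IN dendritic axis points along -x and BA6 along +x
  neurons <- list(
    BA6_PY = .neuron_spec("PY", py_soma, py_dend, g_c_uS = 0.01,
                          axis = c(1, 0, 0)),
    BA4_PY = .neuron_spec("PY", py_soma, py_dend, g_c_uS = 0.01,
                          axis = c(-1, 0, 0)),
    IN = .neuron_spec("IN", in_soma, in_dend, g_c_uS = 0.006,
                      axis = c(-1, 0, 0), VT = -67, EL = -70)
  )
  tuning <- circuit_tuning(condition)
  synapses <- rbind(
    .syn_row("BA6_PY", "BA4_PY", "AMPA", tuning$w_ba6_ba4_ampa, 2),
    .syn_row("BA6_PY", "BA4_PY", "NMDA", tuning$w_ba6_ba4_nmda, 2),
    .syn_row("BA6_PY", "IN",     "AMPA", tuning$w_ba6_in_ampa, 2),
    .syn_row("BA6_PY", "IN",     "NMDA", tuning$w_ba6_in_nmda, 2),
    .syn_row("BA4_PY", "IN",     "AMPA", tuning$w_ba4_in_ampa, 1),
    .syn_row("BA4_PY", "IN",     "NMDA", tuning$w_ba4_in_nmda, 1),
    .syn_row("IN",     "BA4_PY", "GABA_A", tuning$w_in_ba4_gaba, 1,
             target = "soma")
  )
  structure(list(
    condition = condition,
    frequency = if (condition == "alpha") 10 else 20,
    neurons = neurons,
    synapses = synapses,
    poisson = tuning$poisson,
    sweep_increment = tuning$sweep_increment,
    poisson_tau1 = 2, poisson_tau2 = 10,
    dt_ms = dt_ms,
    duration_baseline_s = duration_baseline_s,
    duration_stim_s = duration_stim_s,
    seed = as.integer(seed),
    shared_poisson = shared_poisson,
    reversal = list(E_Na = 50, E_K = -90, E_Ca = 120),
    calcium = list(ca0 = 5e-5, tau_ca = 30, k_ca = 2e-3, kd_ca = 2e-3),
    refractory_ms = 1
  ), class = "circuit_config")
}

#' Synaptic and background tuning constants per condition
#'
#' The per-condition Poisson rates/weights and synaptic weights that set the
#' baseline firing regime. Exposed so sweeps and sensitivity analyses can
#' start from the shipped defaults.
#'
#' @param condition `"alpha"` or `"beta"`.
#' @return named list of weights (uS) and per-neuron Poisson drive.
#' @export
circuit_tuning <- function(condition = c("alpha", "beta")) {
  condition <- match.arg(condition)
  if (condition == "alpha") {
    list(
      poisson = data.frame(
        neuron = CIRCUIT_NEURONS,
        rate_hz = c(3000, 3000, 300),
        w_uS = c(8.5e-5, 5.5e-5, 8e-5)),
      w_ba6_ba4_ampa = 5e-3, w_ba6_ba4_nmda = 1.2e-2,
      w_ba6_in_ampa = 5e-5, w_ba6_in_nmda = 5e-5,
      w_ba4_in_ampa = 5e-5, w_ba4_in_nmda = 5e-5,
      w_in_ba4_gaba = 5e-4,
      sweep_increment = 0.07)
  } else {
    list(
      poisson = data.frame(
        neuron = CIRCUIT_NEURONS,
        rate_hz = c(3000, 3000, 300),
        w_uS = c(2.2e-4, 7.5e-5, 8e-5)),
      w_ba6_ba4_ampa = 1e-2, w_ba6_ba4_nmda = 3e-3,
      w_ba6_in_ampa = 5e-5, w_ba6_in_nmda = 2e-5,
      w_ba4_in_ampa = 5e-5, w_ba4_in_nmda = 5e-5,
      w_in_ba4_gaba = 5e-4,
      sweep_increment = 0.44)
  }
}

#' Uniform-field specification
#'
#' @param amplitude_vm field strength, V/m (default 3).
#' @param frequency_hz sinusoid frequency.
#' @param direction 3-vector, normalized internally.
#' @param t_on_s,t_off_s field span, s (defaults: after the baseline span).
#' @param ramp_s linear on/off ramp, s.
#' @return object of class `field_spec`.
#' @export
field_spec <- function(amplitude_vm = 3, frequency_hz = 10,
                       direction = c(1, 0, 0), t_on_s = NULL,
                       t_off_s = NULL, ramp_s = 10) {
  stopifnot(amplitude_vm >= 0, frequency_hz > 0, length(direction) == 3)
  nrm <- sqrt(sum(direction^2))
  if (nrm == 0) stop("field_spec: zero direction vector")
  structure(list(amplitude_vm = amplitude_vm, frequency_hz = frequency_hz,
                 direction = direction / nrm, t_on_s = t_on_s,
                 t_off_s = t_off_s, ramp_s = ramp_s),
            class = "field_spec")
}

#' Extracellular potential of each compartment under a uniform field
#'
#' `Ve = -E . r` per compartment, with
#' `E(t) = amplitude * envelope(t) * cos(2 pi f (t - t_on)) * direction`
#' (the waveform peak defines stimulation phase 0) and linear ramps of
#' length `ramp_s` at onset and offset. Soma sits at the origin of each
#' neuron; the dendrite ends one dendritic length along the neuron's axis.
#'
#' @param config a [build_default_circuit()] config.
#' @param field a [field_spec()].
#' @param t_s times, s (vectorized).
#' @return data frame: `t_s`, `neuron`, `ve_soma_mv`, `ve_dend_mv`,
#'   `delta_ve_mv` (dendrite minus soma).
#' @export
apply_extracellular_field <- function(config, field, t_s) {
  stopifnot(inherits(config, "circuit_config"), inherits(field, "field_spec"))
  t_on <- field$t_on_s %||% config$duration_baseline_s
  t_off <- field$t_off_s %||% (t_on + config$duration_stim_s)
  if (field$ramp_s > 0) {
    env <- pmax(0, pmin(1, pmin((t_s - t_on) / field$ramp_s,
                                (t_off - t_s) / field$ramp_s)))
  } else {
    env <- rep(1, length(t_s))
  }
  env[t_s < t_on | t_s > t_off] <- 0
  Et <- field$amplitude_vm * env * cos(2 * pi * field$frequency_hz *
                                         (t_s - t_on))
  rows <- lapply(names(config$neurons), function(nm) {
    nr <- config$neurons[[nm]]
    # dendrite tip displacement along the axis, um -> mV per (V/m)
    proj_um <- sum(nr$axis * field$direction) * nr$dend$length_um
    dve <- -Et * proj_um * 1e-3
    data.frame(t_s = t_s, neuron = nm, ve_soma_mv = 0,
               ve_dend_mv = dve, delta_ve_mv = dve)
  })
  do.call(rbind, rows)
}

.neuron_par_matrix <- function(config) {
  vapply(config$neurons, function(nr) {
    gs <- nr$soma$conduct
    gd <- nr$dend$conduct
    uS <- function(mScm2, area) mScm2 * area * 1e3   # mS -> uS
    c(C_s = nr$soma$C_nF, C_d = nr$dend$C_nF, g_c = nr$g_c_uS,
      gNa_s = uS(gs$gNa, nr$soma$area_cm2),
      gKv_s = uS(gs$gKv, nr$soma$area_cm2),
      gKm_s = uS(gs$gKm %||% 0, nr$soma$area_cm2),
      gL_s = uS(gs$gL, nr$soma$area_cm2),
      gCa_s = uS(gs$gCa %||% 0, nr$soma$area_cm2),
      gKCa_s = uS(gs$gKCa %||% 0, nr$soma$area_cm2),
      gL_d = uS(gd$gL, nr$dend$area_cm2),
      EL = nr$EL, VT = nr$VT,
      pol_um = NA_real_,   # filled per field direction
      I_inj = nr$I_inj_nA)
  }, numeric(14))
}

#' Simulate the microcircuit
#'
#' Integrates the coupled two-compartment conductance equations with
#' Hodgkin-Huxley-style kinetics, dual-exponential synapses, seeded Poisson
#' background and the uniform-field drive. Deterministic given
#' `(config, field, seed)`. Spikes are upward 0 mV crossings at the soma
#' with a 1 ms refractory.
#'
#' @param config a [build_default_circuit()] config (`dt_ms <= 0.05`).
#' @param field a [field_spec()] or `NULL` for no stimulation.
#' @param record_voltage_ms sample membrane voltages every this many ms
#'   (`0` = do not record).
#' @return object of class `simulation_result`: `spike_times` (list, s),
#'   `t_on_s`, `t_off_s`, `frequency_hz`, `config`, optional `voltages`.
#' @export
simulate_circuit <- function(config, field = NULL, record_voltage_ms = 0) {
  stopifnot(inherits(config, "circuit_config"))
  if (config$dt_ms > 0.05) stop("simulate_circuit: dt must be <= 0.05 ms")
  t_total_s <- config$duration_baseline_s + config$duration_stim_s
  if (t_total_s <= 0) stop("simulate_circuit: nonpositive duration")
  pars <- .neuron_par_matrix(config)
  if (is.null(field)) {
    amp <- 0; freq <- config$frequency
    t_on <- t_total_s; t_off <- t_total_s; ramp <- 0
    pars["pol_um", ] <- 0
  } else {
    stopifnot(inherits(field, "field_spec"))
    amp <- field$amplitude_vm
    freq <- field$frequency_hz
    t_on <- field$t_on_s %||% config$duration_baseline_s
    t_off <- field$t_off_s %||% (t_on + config$duration_stim_s)
    ramp <- field$ramp_s
    pars["pol_um", ] <- vapply(config$neurons, function(nr) {
      sum(nr$axis * field$direction) * nr$dend$length_um
    }, numeric(1))
  }
  syn <- config$synapses
  syn_cpp <- data.frame(
    pre = match(syn$pre, CIRCUIT_NEURONS) - 1L,
    post = match(syn$post, CIRCUIT_NEURONS) - 1L,
    post_comp = syn$post_comp, is_nmda = syn$is_nmda,
    E = syn$E, tau1 = syn$tau1, tau2 = syn$tau2, w = syn$w,
    delay = syn$delay)
  po <- config$poisson[match(CIRCUIT_NEURONS, config$poisson$neuron), ]
  raw <- simulate_circuit_cpp(
    pars, syn_cpp, po$rate_hz, po$w_uS,
    config$poisson_tau1, config$poisson_tau2,
    config$dt_ms, t_total_s * 1000,
    amp, freq, t_on * 1000, t_off * 1000, ramp * 1000,
    config$seed, config$shared_poisson, record_voltage_ms,
    config$reversal$E_Na, config$reversal$E_K, config$reversal$E_Ca,
    config$calcium$ca0, config$calcium$tau_ca, config$calcium$k_ca,
    config$calcium$kd_ca, config$refractory_ms)
  spikes <- lapply(raw$spike_times_ms, function(x) x / 1000)
  names(spikes) <- CIRCUIT_NEURONS
  out <- list(spike_times = spikes, t_on_s = t_on, t_off_s = t_off,
              frequency_hz = freq, field_amplitude_vm = amp,
              duration_s = t_total_s, config = config)
  if (record_voltage_ms > 0) {
    out$voltages <- list(t_s = raw$voltage_t_ms / 1000,
                         soma = stats::setNames(raw$voltage_soma,
                                                CIRCUIT_NEURONS),
                         dend = stats::setNames(raw$voltage_dend,
                                                CIRCUIT_NEURONS))
  }
  structure(out, class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  rates <- vapply(x$spike_times, function(s) length(s) / x$duration_s,
                  numeric(1))
  cat(sprintf("<simulation_result> %.0f s (%s), rates: %s spikes/s\n",
              x$duration_s, x$config$condition,
              paste(sprintf("%s %.1f", names(rates), rates),
                    collapse = ", ")))
  invisible(x)
}

#' Baseline firing rates of a config
#'
#' Convenience: simulate without a field and report spikes/s per neuron.
#'
#' @param config a `circuit_config`.
#' @return named numeric vector of rates.
#' @export
baseline_rates <- function(config) {
  res <- simulate_circuit(config, field = NULL)
  vapply(res$spike_times, function(s) length(s) / res$duration_s,
         numeric(1))
}

# stimulation phase (deg) of spike times during the field span; outside the
# span, the virtual waveform at the same frequency is used
.stim_phases <- function(times, t_ref, freq) {
  wrap_deg(360 * ((freq * (times - t_ref)) %% 1))
}

#' Per-neuron entrainment report (baseline vs stimulation)
#'
#' PLV, preferred phase and firing rate per span; baseline phases are taken
#' against the virtual waveform (same frequency, same phase origin).
#'
#' @param result a [simulate_circuit()] result.
#' @return data frame with one row per neuron and span.
#' @export
entrainment_report <- function(result) {
  stopifnot(inherits(result, "simulation_result"))
  spans <- data.frame(span = c("baseline", "stimulation"),
                      start = c(0, result$t_on_s),
                      end = c(result$t_on_s, result$t_off_s))
  spans <- spans[spans$end > spans$start, ]
  rows <- lapply(names(result$spike_times), function(nm) {
    tt <- result$spike_times[[nm]]
    do.call(rbind, lapply(seq_len(nrow(spans)), function(i) {
      s <- spans[i, ]
      st <- tt[tt >= s$start & tt < s$end]
      if (length(st) == 0) {
        return(data.frame(neuron = nm, span = s$span, n_spikes = 0L,
                          rate_hz = 0, plv = NA_real_,
                          preferred_phase = NA_real_))
      }
      ph <- .stim_phases(st, result$t_on_s, result$frequency_hz)
      cs <- circular_summary(phase_sample(ph, unit = "deg"))
      data.frame(neuron = nm, span = s$span, n_spikes = length(st),
                 rate_hz = length(st) / (s$end - s$start), plv = cs$plv,
                 preferred_phase = cs$preferred_phase)
    }))
  })
  do.call(rbind, rows)
}

#' Synaptic-weight (plasticity) sweep
#'
#' Runs `n_trials` stimulations; in trial `k` (k = 0 .. n_trials - 1) the
#' swept synaptic weight is `w0 * (1 + k * increment)` while everything else
#' stays fixed, emulating progressive long-term potentiation of that
#' connection. Per trial the BA4-PY spike phases during stimulation are
#' summarized (PLV, preferred phase) against the stimulation waveform.
#'
#' @param config a `circuit_config`.
#' @param field a [field_spec()]; frequency should match the condition.
#' @param n_trials number of weight steps (default 20).
#' @param increment fractional weight increase per step; `NULL` (default)
#'   uses the condition's plasticity schedule from the config
#'   (`sweep_increment`).
#' @param synapse which connection to sweep: `"nmda"` (BA6-PY to BA4-PY
#'   NMDA, the plasticity hypothesis) or `"gaba"` (IN to BA4-PY GABA_A, the
#'   control).
#' @param reseed_trials give each trial its own Poisson substream when
#'   `TRUE` (default); `FALSE` reuses one realization across trials.
#' @param neuron neuron whose phases are summarized (default `"BA4_PY"`).
#' @return data frame: `trial`, `weight_uS`, `n_spikes`, `plv`,
#'   `preferred_phase` (deg), `rate_hz`; attribute `results` holds the raw
#'   `simulation_result`s invisibly.
#' @export
nmda_weight_sweep <- function(config, field, n_trials = 20,
                              increment = NULL,
                              synapse = c("nmda", "gaba"),
                              reseed_trials = TRUE, neuron = "BA4_PY") {
  synapse <- match.arg(synapse)
  stopifnot(inherits(config, "circuit_config"), n_trials >= 2)
  if (is.null(increment)) increment <- config$sweep_increment
  sel <- if (synapse == "nmda") {
    which(config$synapses$pre == "BA6_PY" & config$synapses$post == "BA4_PY" &
            config$synapses$receptor == "NMDA")
  } else {
    which(config$synapses$pre == "IN" & config$synapses$post == "BA4_PY" &
            config$synapses$receptor == "GABA_A")
  }
  stopifnot(length(sel) == 1)
  w0 <- config$synapses$w[sel]
  factors <- 1 + (seq_len(n_trials) - 1) * increment
  if (any(w0 * factors < 0)) stop("nmda_weight_sweep: negative weight")
  rows <- vector("list", n_trials)
  for (k in seq_len(n_trials)) {
    cfg <- config
    cfg$synapses$w[sel] <- w0 * factors[k]
    if (reseed_trials) cfg$seed <- config$seed + 7919L * k
    res <- simulate_circuit(cfg, field)
    tt <- res$spike_times[[neuron]]
    st <- tt[tt >= res$t_on_s & tt < res$t_off_s]
    if (length(st) >= 2) {
      ph <- .stim_phases(st, res$t_on_s, res$frequency_hz)
      cs <- circular_summary(phase_sample(ph, unit = "deg"))
      plv <- cs$plv; pref <- cs$preferred_phase
    } else {
      plv <- NA_real_; pref <- NA_real_
    }
    rows[[k]] <- data.frame(trial = k, weight_uS = w0 * factors[k],
                            n_spikes = length(st), plv = plv,
                            preferred_phase = pref,
                            rate_hz = length(st) /
                              (res$t_off_s - res$t_on_s))
  }
  do.call(rbind, rows)
}

#' Total phase shift of a sweep trajectory
#'
#' Robust summary of how far a sweep's preferred phase travels: the
#' per-trial phases are unwrapped (cumulative minimal angular steps) and a
#' least-squares line against trial index is fitted; the total shift is the
#' fitted slope times the trial span. Less sensitive to single-trial phase
#' noise than the raw last-minus-first difference.
#'
#' @param sweep a [nmda_weight_sweep()] result (or any data frame with
#'   `trial` and `preferred_phase` in degrees).
#' @return signed total shift in degrees (positive = counter-clockwise).
#' @export
sweep_total_shift <- function(sweep) {
  ok <- is.finite(sweep$preferred_phase)
  ph <- sweep$preferred_phase[ok]
  tr <- sweep$trial[ok]
  if (length(ph) < 2) return(NA_real_)
  steps <- angular_difference(ph[-length(ph)], ph[-1])
  unwrapped <- ph[1] + c(0, cumsum(steps))
  fit <- stats::lm(unwrapped ~ tr)
  unname(stats::coef(fit)[2]) * (max(tr) - min(tr))
}

#' Write circuit spikes to CSV (neuron, time_s)
#'
#' @param result a `simulation_result`.
#' @param path output CSV.
#' @export
write_circuit_spikes_csv <- function(result, path) {
  stopifnot(inherits(result, "simulation_result"))
  df <- do.call(rbind, lapply(names(result$spike_times), function(nm) {
    data.frame(neuron = nm, time_s = result$spike_times[[nm]])
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
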