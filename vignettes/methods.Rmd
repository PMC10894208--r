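---
title: "Models and methods behind acprecess"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind acprecess}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the statistical conventions, the preprocessing and classification
procedures, the microcircuit model and how it was parameterized, what the
synthetic-data generators do and do not emulate, and the numerical choices
that matter. Nothing here states an empirical result that the test suite
or `scripts/acceptance.R` does not itself compute.

## Phase conventions and circular statistics

All phases are referenced to the stimulation waveform with **0° at the
waveform peak** and 180° at the trough; angles increase counter-clockwise.
Internally everything is radians; every interface speaks degrees. A
"clockwise" phase shift is negative (spiking moves earlier in the cycle),
"counter-clockwise" positive (later in the cycle).

The phase-locking value of a spike train is the resultant length
$\mathrm{PLV} = |\tfrac{1}{N}\sum_k e^{i\theta_k}|$; the preferred phase is
the argument of the same resultant. A zero resultant (antipodal or uniform
phases) leaves the preferred phase *undefined*, which the package reports
as an explicit flag rather than a silent `NA` or 0 — downstream code must
decide what to do with such windows.

The Rayleigh test uses $Z = nR^2$ with the standard small-sample corrected
tail $p = \exp\!\big(\sqrt{1 + 4n + 4(n^2 - R_n^2)} - (1 + 2n)\big)$,
$R_n = nR$. The correction's exact form is a package choice (the classical
Berens-toolbox form); at the sample sizes the pipelines use (tens to
hundreds of spikes per window) it is indistinguishable from the
uncorrected $e^{-Z}$ beyond the third decimal. Its type-I behaviour is
verified empirically in the test suite (2000 uniform null draws at
n = 50).

The circular–linear correlation composes the three Pearson correlations
$r_{cx}, r_{sx}, r_{cs}$ of $(\cos\theta, x)$, $(\sin\theta, x)$,
$(\cos\theta, \sin\theta)$; its square equals the $R^2$ of the regression
of $x$ on $(\cos\theta, \sin\theta)$, which the tests use as an
independent oracle. Significance comes from a $\chi^2(2)$ tail on $nr^2$.
With constant phases the statistic is undefined and the function errors;
a phase sample constant in one coordinate only degrades gracefully to the
single remaining Pearson correlation.

## Spike preprocessing

The detection chain mirrors standard extracellular practice: spectral
interpolation of narrow stimulation-artifact bands, a zero-phase 4th-order
Butterworth band-pass at 300–3000 Hz, amplitude thresholding at
$\lambda\sigma_n$ with the robust noise scale
$\sigma_n = \mathrm{median}(|x|)/0.6745$ and $\lambda = 4$, alignment of
each event on its dominant extremum (either polarity), and 32-sample
snippets (8 before the extremum, 24 after).

Choices worth knowing:

* **Spectral interpolation** operates on the amplitude spectrum: bins
  within ±`halfwidth` (default 0.5 Hz) of each target frequency are
  rescaled to the linear interpolation of the mean amplitudes in the
  flanking bands of the same width, phases untouched, conjugate symmetry
  restored, inverse FFT taken. This suppresses the artifact line to the
  level of its spectral neighbourhood without ringing in time.
* **Zero-phase filtering** (forward–backward) is used so that spike times
  are not biased by filter group delay.
* **Censor window**: after each accepted event, detections are suppressed
  for 1.6 ms — the snippet span — so a single waveform (including the
  rebound lobe that zero-phase filtering spreads out) cannot be counted
  twice. A shorter, purely "refractory" censor of 1 ms demonstrably
  double-counts strong spikes after filtering.
* **Noise floor**: at $\lambda = 4$, pure Gaussian noise crosses threshold
  at a rate of $2\Phi(-4)$ per sample; over minutes of wideband recording
  this produces a handful of spurious sub-threshold-amplitude events.
  That is a property of the thresholding method itself, not a bug; the
  tests bound the spurious count by the analytic exceedance rate, and in
  real use the downstream clustering step removes these events.
* The cluster SNR uses the *sample* standard deviation of each waveform's
  residual around the cluster mean; SNR is invariant under common
  rescaling of all waveforms, and a cluster of identical waveforms is an
  error (degenerate noise estimate), not an infinite SNR.

## The sliding-window precession framework

Spikes are assigned phases either against an ideal sinusoid at the block
frequency or against a narrow-band (±1 Hz, 2nd-order Butterworth,
zero-phase) filtered field recording whose analytic-signal phase is mapped
so the waveform peak is 0°. Ramp periods (default 10 s) at block edges are
excluded from phase assignment.

The canonical windowing is 132 s windows advancing in 12 s steps, 20
windows over a 360 s block, pooled across four blocks at matched window
index (pooling spikes, the default, is exactly equivalent to averaging
when blocks are statistically identical — a property the tests check).
Windows with fewer than 10 spikes are non-responsive by fiat: a Rayleigh
test on fewer events is uninformative.

Classification is the three-step gate described in the README. Two
details:

* The total shift is computed on the *unwrapped* sequence of preferred
  phases (cumulative minimal angular steps between consecutive responsive
  windows), so a drift through 360° is not aliased by a naive
  last-minus-first difference.
* Because windows are wide, the measurable drift span is the distance
  between the first and last window *centres* — 228 s of a 360 s block —
  so a linear drift of $d$ degrees across the block appears as roughly
  $0.63\,d$ in the track. Tests and calibration always state which of the
  two quantities they plant.

Units failing the circular–linear gate are labelled `stable` when their
total shift is within the threshold and `non-uniform` otherwise
(multi-directional wandering); units passing the gate but below the 15°
shift threshold are `stable`.

## The MEP pipeline

Motor-evoked-potential amplitudes are normalized per block (dividing by
the block mean removes between-block gain and the block-boundary reset),
averaged per probed phase, and condensed into the polar excitability
vector with Cartesian convention $x = M(180°) - M(0°)$,
$y = M(270°) - M(90°)$. Under this convention the amplitude-weighted
circular mean of the four phase means equals
$\mathrm{atan2}(y, x) + 180°$, which is how the preferred phase is
reported: a session whose excitability peaks at 90° yields a preferred
phase of 90°. The sliding track uses 55-trial windows stepping 5 trials,
20 windows per block, polar vectors averaged *as vectors* (mean x, mean y)
across blocks at matched window index.

The permutation null shuffles phase labels within each block, preserving
amplitudes and trial order, and recomputes the entire windowed track and
its drift correlation per permutation. This null matters because
neighbouring windows share 50 of 55 trials: a no-signal track is a smooth
random walk whose circular–linear correlation with window index is often
large, so the raw drift p-value flatters the evidence. The permutation
p-value is the fraction of null correlations at or above the observed one.

Trials with zero amplitude (no response) are retained; the pipeline makes
no rejection decisions.

## The microcircuit model

Three neurons: BA6-PY (premotor), BA4-PY (primary motor), and a
fast-spiking interneuron. Each is a two-compartment (soma + passive
dendrite) conductance-based cell; the two pyramidal cells are identical
with **anti-parallel** somatodendritic axes, and the interneuron shares
BA4's orientation. Pyramidal somata carry fast Na, delayed-rectifier K,
slow non-inactivating K (muscarinic-type), high-threshold Ca, and a
Ca-dependent K current fed by a first-order calcium pool
(τ = 30 ms) with instantaneous activation Ca/(Ca + K_D); the interneuron
carries Na, K and leak only. Rate functions are the standard
Traub/Pospischil forms with a threshold-shift parameter VT. All
morphology, conductance and synaptic constants are package defaults,
fully exposed in the config object, since no external parameter tables
are bundled.

Synapses are peak-normalized dual exponentials (rise τ₁, decay τ₂):
AMPA 0.5/3 ms at 0 mV, NMDA 8/65 ms at 0 mV with the sigmoidal 1 mM
Mg²⁺-block factor, GABA_A 0.5/8 ms at −80 mV. Excitatory synapses contact
the dendrite, the inhibitory synapse the soma. Connectivity: BA6→BA4 and
BA6→IN (AMPA + NMDA, 2 ms delay — the premotor-to-motor projection),
BA4↔IN reciprocal with 1 ms local delays (BA4→IN excitatory, IN→BA4
GABA_A). Poisson background (0 mV, 2/10 ms) drives every cell;
independent per-neuron streams derive from one master seed (a
shared-realization mode exists).

The uniform field enters through the extracellular potential
$V_e = -\vec E \cdot \vec r$: for a compartment pair separated by $L$
along the axis, the membrane equation receives
$\Delta V_e = -E(t)\,(\hat u \cdot \hat d)\,L$, with
$E(t) = A\,\mathrm{env}(t)\cos(2\pi f (t - t_\mathrm{on}))$ and linear
on/off ramps (default 10 s). The cosine convention puts the waveform peak
at phase 0, consistent with the package-wide phase convention; with a
ramped onset the choice of cosine versus sine is a pure relabelling of
time. At 3 V/m along the 500 µm pyramidal axis the peak extracellular
difference is 1.5 mV and the resulting somatic polarization ≈ 1.2 mV at
10 Hz, which the tests verify against the closed-form complex two-node RC
solution.

### How the conditions are tuned, and why

The design target is behavioural: baseline pyramidal rates near
10 spikes/s (alpha) or 17 spikes/s (beta), and a counter-clockwise
trajectory of the motor cell's preferred phase (roughly 90° to 150° at
10 Hz, ending near 180° at 20 Hz) under the NMDA-weight sweep. The shipped tuning achieves this as follows.

**Alpha (10 Hz).** Both pyramidal cells are *mean-driven regular
oscillators*: high-rate (3 kHz), small-amplitude Poisson drive plus the
somatic afterhyperpolarization makes them fire rhythmically with low ISI
variability. BA6-PY's intrinsic rate sits just above 10 Hz, so the 3 V/m
field locks it 1:1 with a substantial phase *lead* (~75° before its
depolarization peak at 180°) — the classic behaviour of a
slightly-detuned oscillator inside its locking tongue. BA4-PY's own drive
is set below oscillation threshold: it fires when triggered. At the base
NMDA weight the fast AMPA component of each BA6 volley triggers it
(~100°); as the swept NMDA weight grows, the slow NMDA tail increasingly
produces additional, later spikes, and the preferred phase rotates
counter-clockwise toward ~145–150°. Sweeping the GABA_A weight instead
changes the depth of inhibition but not the *timing* of the drive, so the
phase stays put — the mechanism behind the flat inhibitory control.

**Beta (20 Hz).** Locking requires the oscillator's intrinsic rate near
the stimulation frequency, so the premotor cell is tuned to ~20.4
spikes/s (locking at 20 Hz with a lead) while the motor cell follows its
volleys partially at ~13.4 spikes/s; the *mean* pyramidal baseline is
~16.9 spikes/s, matching the low-beta tuning target. This is a deliberate
deviation from tuning both cells to 17: a 17 Hz oscillator under a 20 Hz
field sits outside the locking tongue, phase-walks, and produces no
reproducible phase trajectory at all — whereas the condition's tuning
principle (cells susceptible to stimulation fire near the stimulation
frequency) is preserved by the premotor cell.

The sweep multiplies the base NMDA weight by $1 + k\cdot\mathrm{inc}$ for
trials $k = 0..19$; the per-condition increments (0.07 alpha, 0.44 beta)
are the package's plasticity schedule. Each trial reseeds its Poisson
streams (a shared-realization mode exists for variance-matched
comparisons).

### Numerics

Gating variables advance by exponential Euler; the two membrane voltages
advance by an implicit backward-Euler 2×2 solve per neuron per step with
conductances frozen at the current gating state, which keeps the stiff
spike currents stable at dt = 0.025 ms (halving dt changes 30 s spike
counts by under 2%, a tested property). Poisson event times are drawn as
exponential inter-arrival increments, so the event stream is independent
of dt. Spikes are upward 0 mV crossings at the soma with a 1 ms refractory
guard; a voltage excursion beyond ±200 mV aborts with the offending time.
Everything is deterministic given (config, field, seed).

Simulation spans in the tests and acceptance script are 60–120 s per run
or trial; these are the package's desk-scale defaults, long enough that a
preferred-phase estimate carries a standard error of a few degrees at the
observed locking strengths. The configurable defaults for a full protocol
(6 min baseline + 6 min stimulation) match the block structure of the
stimulation experiments this chain is designed for.

## What the generators emulate — and what they do not

`gen_spike_train` produces homogeneous-rate spikes whose phases are von
Mises around a linearly drifting preferred phase; rate and phase are
generated independently, matching the observation that stimulation shifts
phase without changing rate. It does not model refractoriness, bursting,
rate adaptation, or phase–rate coupling. `gen_extracellular_trace` places
stereotyped templates in white Gaussian noise with an optional sinusoidal
artifact; real electrode noise is coloured and spikes vary in shape, so
detection performance on real data will be somewhat worse than the tested
fixtures. `gen_mep_series` uses multiplicative lognormal amplitude noise
(MEPs are positive and right-skewed) with cosine phase tuning and an
optional within-block linear trend; it does not model inter-subject
variability or serial correlation between trials. Tests passing on these
fixtures therefore validate the *computational chain* — not the
recording-specific robustness of any step.

## Known limitations

* The microcircuit is one cell per population; network-level phenomena
  (oscillation generation, inhibition-stabilized dynamics across layers)
  are out of scope, and the beta-condition trajectory is noisier than
  alpha because the motor cell is only partially entrained there.
* The spectral-interpolation artifact remover assumes a stationary
  narrow-band artifact; transient or broadband artifacts need different
  tools.
* The classifier's shift estimate is attenuated by the window span
  (~0.63 of the planted per-block drift under the canonical windowing);
  comparisons across windowing schemes must account for this.
* No spike sorting is provided beyond thresholding, alignment and SNR;
  overlapping units on one channel are not separated.
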