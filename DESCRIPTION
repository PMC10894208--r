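Package: acprecess
Title: Phase Entrainment and Induced Phase Precession Under Alternating-Current Stimulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Circular statistics (phase-locking value, Rayleigh test,
    circular-linear correlation), extracellular spike preprocessing
    (spectral artifact interpolation, Butterworth band-pass, amplitude
    thresholding, cluster signal-to-noise ratio), a sliding-window
    phase-precession classification framework for single units, a
    macroscale motor-evoked-potential phase-drift analysis with a
    permutation null, a two-compartment conductance-based cortical
    microcircuit simulator with uniform-field coupling and
    synaptic-weight sweeps, and seeded synthetic-data generators that
    emulate the statistical structure each pipeline assumes.
License: MIT
Encoding: UTF-8
Imports:
    signal,
    stats,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
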