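Package: phasestim
Title: Closed-Loop Phase-Dependent Vibrotactile Stimulation for Motor-Imagery EEG
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for simulating and analysing closed-loop, EEG
    phase-dependent vibrotactile stimulation experiments. Provides a
    synthetic-EEG generator with injectable event-related
    desynchronization (ERD), a streaming FFT-based alpha-phase tracker
    with forward prediction, a phase-interval-gated stimulus scheduler
    with refractory and amplitude-pattern rules, offline validation via
    the Hilbert analytic signal and the phase-locking value (PLV),
    event-related spectral perturbation (ERSP) and band-energy analyses,
    and a filter-bank common spatial pattern (FBCSP) plus linear
    discriminant analysis classification pipeline with repeated
    cross-validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
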