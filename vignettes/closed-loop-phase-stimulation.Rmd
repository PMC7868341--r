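---
title: "Closed-loop phase-dependent vibrotactile stimulation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Closed-loop phase-dependent vibrotactile stimulation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(phasestim)
```

## The problem

Motor-imagery (MI) brain-computer interfaces decode the event-related
desynchronization (ERD) of the sensorimotor mu/alpha rhythm (8-13 Hz)
that accompanies imagined movement. A sizeable fraction of users produce
weak ERD ("BCI illiteracy"). One remedial strategy is to pair the
imagery with vibrotactile stimulation, and — because the effect of a
stimulus depends on the oscillatory phase at which it arrives — to
*gate* each vibration pulse on the predicted instantaneous phase of the
ongoing alpha rhythm: a closed loop of EEG acquisition, real-time phase
forecasting, and phase-windowed stimulus triggering.

`phasestim` implements that loop end to end as a testable library:

1. **synth** — a synthetic-EEG generator with injectable ERD, so every
   downstream stage has ground truth;
2. **tracker** — streaming FFT-based alpha-phase estimation with
   forward prediction;
3. **scheduler** — phase-interval gating with refractory and
   amplitude-pattern rules, plus stimulus waveform synthesis;
4. **eval** — offline Hilbert ground truth, phase-locking value (PLV),
   rose-histogram data, trial rejection;
5. **spectral** — trial-averaged ERSP, band ERD/ERS, sliding
   band-energy curves, common-average reference;
6. **classify** — FBCSP + LDA with repeated stratified
   cross-validation;
7. **io_cli** — a text array container, report writers, and a CLI
   (`inst/cli/phasestim.R`).

## Phase convention

All modules share the *sine* convention: phase 0 is the ascending zero
crossing, so `x(t) = A sin(phi(t))`. The rising gating interval
`[-pi/6, pi/3]` brackets the ascending zero crossing and the falling
interval `[5 pi/6, 4 pi/3]` the descending one. The analytic-signal
angle (cosine convention) is converted by adding `pi/2`.

## The streaming phase tracker

Every 40 ms the latest 300 ms of the target channel (C4) are analyzed:

1. causal 8-12 Hz bandpass, 10th-order elliptic IIR;
2. FFT of the segment (zero-padded to 2048 points);
3. frequency and phase of the dominant spectral component;
4. sinusoidal extrapolation `phi(t + h) = phi(t) + 2 pi f_dom h` with a
   forecast horizon `h` (default 40 ms, one update interval).

Numerical choices, made where the method statement leaves them open:

* **Elliptic design parameters.** Ripple/attenuation are unstated in
  the source method; the package fixes 0.5 dB passband ripple and 50 dB
  stopband attenuation. The design is computed from the analog Cauer
  prototype (Jacobi elliptic functions via Landen recursions), warped
  through the lowpass-to-bandpass and bilinear transforms.
* **Second-order sections.** A single `(b, a)` transfer function of a
  10th-order bandpass with a 4 Hz passband at 1000 Hz is numerically
  unusable (coefficient cancellation distorts the response by orders of
  magnitude); filters are therefore stored and applied as cascaded
  biquads.
* **Continuous causal filtering.** The original design idea of
  re-filtering each 300 ms window from a zero filter state fails for
  this filter: its poles sit at radius ~0.998, so the onset transient
  rings through the entire window and the phase estimate is destroyed
  (PLV ~ 0.72 against ground truth on a *noiseless* sinusoid). The
  tracker instead runs one forward-only pass whose state persists
  across hops — exactly what a real-time system does, and still
  strictly causal: truncating the recording after an estimate's last
  used sample leaves all earlier estimates bit-identical (this is a
  tested property).
* **Hann analysis taper.** The windowed segment is tapered before the
  FFT. This both controls spectral leakage — making parabolic
  interpolation of the peak bin accurate to ~0.01 Hz on a stationary
  tone — and down-weights the early window samples, where any residual
  transient lives. Ties between equal-magnitude bins break toward the
  lower frequency.
* **Filter-phase compensation.** The causal filter delays the phase by
  `Arg H(f)`; since the filter is the package's own design, this is
  compensated exactly at the estimated dominant frequency. The
  remaining, irreducible latency is physical: the window centroid
  (~150 ms) plus the filter group delay (~250 ms) plus the forecast
  horizon. Phase diffusion of real (and synthetic) alpha over that
  ~0.4 s is what keeps the PLV meaningfully below 1.
* **Horizon.** The latency the forecast should cover is
  hardware-dependent and unstated; the default equals one hop (40 ms)
  and is configurable.

## The scheduler

A pulse fires at an estimate whose forecast phase lies in the target
interval, provided at least 100 ms (configurable) have elapsed since
the previous pulse — the source description says "more than 100 ms",
implemented as a `>= 100 ms` refractory. Amplitude factors follow the
tic-tic-toc pattern `1, 1, 1.5, ...` as a running counter over all
emitted pulses (not reset per alpha cycle or per trial). Pulses are
restricted to the 5-9 s task window of each trial when the trial
structure is supplied. Waveforms: 20 ms, 200 Hz tone bursts with 2 ms
raised-cosine edges; the open-loop condition uses envelope (not ring)
modulation, `m(t) = (1 + sin(2 pi 23 t)) / 2`, because a voice-coil
tactor follows the audio amplitude — the non-negative envelope yields
spectral lines at 177/200/223 Hz.

## Offline validation

Ground-truth phase is the angle of the analytic signal after a
*zero-phase* (forward-backward) elliptic bandpass — deliberately
different from the tracker's causal filter, so the oracle carries no
group delay. PLV compares the forecast phase at each estimate's target
time with the Hilbert phase at that same sample. Because the
aggregation level of the printed fidelity number is unstated in the
source, the benchmark (`plv_benchmark()`) reports per-session values
alongside their mean. Trial rejection removes trials whose fraction of
out-of-interval pulses exceeds 0.5 (threshold unstated in the source;
exposed as a parameter).

## ERSP and band energy

`ersp()` averages per-trial Hann-tapered STFT power (200 ms windows,
50 ms hop — the hop is unstated in the source and fixed here), converts
to dB, and subtracts each frequency's mean dB over the 3-4 s baseline.
Whether the source subtracted in dB or divided linear power before
conversion is unstated; dB-domain subtraction (log-ratio) was chosen as
the common ERSP practice. Consequences: the baseline rows are exactly
0 dB, and any frequency-dependent constant gain cancels. The linear
trial-averaged power is kept on the object (`$power`), where the
trial-set linearity of the average is exact and tested.
`band_energy_curve()` computes total 8-30 Hz energy (summed over FFT
bins, so disjoint sub-band curves add up to the full-band curve) in 1 s
windows hopped 200 ms. Epoch time origin is the trial start (t = 0); task onset is at
5 s; energy curves are reported relative to task onset.

## FBCSP + LDA

Six 4 Hz sub-bands (8-12 ... 28-32 Hz), zero-phase 4th-order
Butterworth per band (an offline stage, so acausal filtering is
deliberate). Per band, trace-normalized per-trial covariances are
averaged by class and jointly diagonalized; whitening is performed in
the signal subspace, dropping numerically null directions — the
common-average reference removes exactly one dimension from a
27-channel montage, and keeping it would inject a spurious
infinite-variance filter. `m = 3` filter pairs per band give 36
log-variance features; classification is ridge-stabilized Fisher LDA.
Cross-validation is 10 repeats of stratified 10-fold; CSP and LDA are
refitted on each training fold (sub-band filtering is fold-independent
and precomputed once). Mutual-information feature selection, present in
the FBCSP literature but not in the method replicated here, is not
applied. The report keeps every fold and repeat rather than selecting a
best configuration, because what the "best averaged accuracy" in the
source ranges over is ambiguous.

## What the synthetic generator emulates — and what it does not

Each session: 27-channel 10/20 montage (C3/C4 included), 1000 Hz,
11 s trials with the task at 5-9 s, balanced MI/rest classes in random
order. Channels contain unit-variance 1/f noise (spectral shaping,
exponent 1). C3 and C4 carry narrowband alpha sources — a sinusoid with
random-walk phase jitter and slowly drifting log-normal envelope,
band-limited to the peak +/- 3 Hz because Wiener phase noise otherwise
has Lorentzian tails that leak the injected ERD into high frequencies —
mixed across the montage by a fixed random full-rank matrix (condition
number capped at 100, redrawn otherwise) so that spatial filtering is
meaningful. During MI task windows the C4 (contralateral to the
imagined left hand) source amplitude is multiplied by `1 - erd_depth`
with 100 ms smoothed edges, so band power drops by `(1 - erd_depth)^2`.

Defaults and their rationale:

* `alpha_snr_db = 10`: in-channel alpha-to-broadband-noise power ratio.
  Real subjects' alpha SNR was not characterized in the source; this
  value is a stated *generator* default, not an estimate of anyone's
  data.
* `phase_jitter_sd = sqrt(2 pi 0.1 / fs)`: a ~0.1 Hz phase-diffusion
  linewidth. Chosen once, from the latency argument above: the spec for
  this generator directs that jitter make phase forecasting non-trivial
  but keep the printed fidelity target achievable; with the method's
  mandatory ~0.4 s latency this linewidth predicts PLV ~ 0.8.
  Substantially coarser jitter would make the printed value physically
  unattainable for any tracker of this design.
* C3's alpha peak sits 0.5 Hz above C4's — a realistic
  inter-hemispheric difference that also keeps the two sources
  empirically uncorrelated over a session.

Not modeled: steady-state somatosensory responses to the vibration
itself, eye/muscle artifacts, electrode drift, volume-conduction
geometry, and any physiological effect of stimulation on the EEG (the
generator's ERD is injected, not induced). A green end-to-end test
therefore establishes that the *pipeline* recovers what was injected at
realistic SNR — not that stimulation modulates real cortex.

## Degenerate inputs and tie-breaks

All-zero tracker windows raise an undefined-phase error; single-channel
recordings cannot be common-average referenced; empty estimate streams
schedule zero events and produce all-zero rose histograms; `n = 1` ERSP
equals the single trial's normalized spectrogram; CSP refuses fewer
than two trials per class and falls back to shrinkage (with a warning)
only when the composite covariance is deficient beyond the structural
CAR null space.

## Known limitations

* The tracker's accuracy inherits the elliptic filter's ~250 ms group
  delay; trackers with lighter filters would forecast better, but the
  point here is fidelity to the replicated method.
* The EDF interchange route is not implemented (no EDF codec exists in
  the dependency environment); the text container + sidecar fills the
  "plain array with sampling-rate/channel-label sidecar" input route.
* Subject-level claims of the original study (accuracy gains under
  stimulation, ERSP topographies of real subjects) are out of reach by
  construction: they require the undeposited recordings.
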