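# Synthetic EEG sessions for closed-loop phase-stimulation experiments.
#
# The generator emulates a sensorimotor-rhythm motor-imagery session: a
# 27-channel 10/20 montage sampled at 1000 Hz, 11 s trials with the task
# in seconds 5-9, an ~10 Hz alpha rhythm over the central channels whose
# amplitude drops (ERD) contralaterally during motor-imagery trials, 1/f
# background noise in every channel, and a fixed full-rank spatial mixing
# of the class-dependent sources so that spatial filters (CSP) have
# something to find.

#' Default 27-channel montage
#'
#' Fronto-central/centro-parietal subset of the 10/20 extended system,
#' covering the sensorimotor strip; includes C3 and C4.
#' @return Character vector of 27 channel labels.
#' @export
default_montage <- function() {
  c("F1", "Fz", "F2",
    "FC5", "FC3", "FC1", "FCz", "FC2", "FC4", "FC6",
    "C5", "C3", "C1", "Cz", "C2", "C4", "C6",
    "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6",
    "P1", "Pz", "P2")
}

#' Configuration for the synthetic-EEG generator
#'
#' @param n_channels Number of channels (default 27; must match the
#'   montage length when `channel_labels` is given).
#' @param fs Sampling rate in Hz (default 1000).
#' @param n_trials Number of trials in the session (default 40, i.e. one
#'   run of the paradigm; classes are balanced).
#' @param trial_len Trial length in seconds (default 11).
#' @param task_window Start/end of the imagery task within the trial, in
#'   seconds (default `c(5, 9)`).
#' @param alpha_freq Mean alpha frequency in Hz (default 10).
#' @param alpha_snr_db Ratio, in dB, of alpha-component variance to the
#'   broadband 1/f background variance in the sensorimotor channels
#'   (default 10).
#' @param erd_depth Fraction in [0, 1) by which the contralateral (C4)
#'   alpha *amplitude* is reduced during the task window of MI trials;
#'   band power drops by `(1 - erd_depth)^2` (default 0.5).
#' @param noise_exponent Spectral slope of the 1/f^a background
#'   (default 1).
#' @param phase_jitter_sd Per-sample standard deviation, in radians, of
#'   the random-walk phase jitter of the alpha sources. The default
#'   `sqrt(2 * pi * 0.1 / fs)` gives a Lorentzian phase-diffusion
#'   linewidth of about 0.1 Hz; together with the envelope drift this
#'   yields an alpha peak of realistic width while keeping forward phase
#'   prediction non-trivial but feasible (the tracker's window, filter
#'   group delay and forecast horizon add up to roughly 0.4 s of
#'   latency over which this diffusion accumulates).
#' @param envelope_drift_sd Standard deviation of the log-envelope drift
#'   of the alpha sources (default 0.25; smoothed below ~0.3 Hz).
#' @param erd_profile `"sustained"` (constant depth across the task
#'   window, the default) or `"ramp"` (depth grows linearly from 0 to
#'   `erd_depth` across the window, emulating a cumulative effect).
#' @param condition Session condition label: one of `"PMI"`, `"CVS"`,
#'   `"RPS"`, `"FPS"` (default `"FPS"`).
#' @param channel_labels Montage labels; must contain `"C3"` and `"C4"`.
#' @param seed Integer seed; the session is fully reproducible from it.
#' @return Object of class `synth_config`.
#' @export
synth_config <- function(n_channels = 27, fs = 1000, n_trials = 40,
                         trial_len = 11, task_window = c(5, 9),
                         alpha_freq = 10, alpha_snr_db = 10,
                         erd_depth = 0.5, noise_exponent = 1,
                         phase_jitter_sd = sqrt(2 * pi * 0.1 / fs),
                         envelope_drift_sd = 0.25,
                         erd_profile = c("sustained", "ramp"),
                         condition = c("FPS", "RPS", "CVS", "PMI"),
                         channel_labels = default_montage(),
                         seed = 1L) {
  erd_profile <- match.arg(erd_profile)
  condition <- match.arg(condition)
  if (length(channel_labels) != n_channels)
    stop("n_channels must match length(channel_labels)")
  if (anyDuplicated(channel_labels))
    stop("channel labels must be unique")
  if (!all(c("C3", "C4") %in% channel_labels))
    stop("montage must contain C3 and C4")
  if (fs <= 2 * (alpha_freq + 5))
    stop("fs must exceed twice the highest synthesized frequency")
  if (erd_depth < 0 || erd_depth >= 1)
    stop("erd_depth must lie in [0, 1)")
  if (task_window[1] < 0 || task_window[2] > trial_len ||
      task_window[2] <= task_window[1])
    stop("task_window must lie within [0, trial_len]")
  if (n_trials < 1) stop("n_trials must be >= 1")
  structure(list(
    n_channels = n_channels, fs = fs, n_trials = n_trials,
    trial_len = trial_len, task_window = task_window,
    alpha_freq = alpha_freq, alpha_snr_db = alpha_snr_db,
    erd_depth = erd_depth, noise_exponent = noise_exponent,
    phase_jitter_sd = phase_jitter_sd,
    envelope_drift_sd = envelope_drift_sd,
    erd_profile = erd_profile, condition = condition,
    channel_labels = channel_labels, seed = as.integer(seed)),
    class = "synth_config")
}

#' Construct an EEG recording object
#'
#' @param data Channels x samples numeric matrix (microvolt-scale
#'   arbitrary units); row names are taken as channel labels when
#'   `channel_labels` is missing.
#' @param fs Sampling rate in Hz.
#' @param channel_labels Character vector of unique 10/20 labels.
#' @param events Data frame with columns `onset_sample` (0-based),
#'   `class` (`"MI"`/`"rest"`) and `condition`; may be empty.
#' @param truth Optional list of generator ground truth (kept as-is).
#' @param config Optional generator configuration.
#' @return Object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs, channel_labels = rownames(data),
                          events = empty_events(), truth = NULL,
                          config = NULL) {
  data <- as.matrix(data)
  if (is.null(channel_labels))
    stop("channel labels are required")
  if (anyDuplicated(channel_labels)) stop("channel labels must be unique")
  if (nrow(data) != length(channel_labels))
    stop("data rows must match channel labels")
  rownames(data) <- channel_labels
  events <- as.data.frame(events)
  if (nrow(events) > 0) {
    if (any(events$onset_sample < 0) ||
        any(events$onset_sample >= ncol(data)))
      stop("event onsets must lie within the recording")
  }
  structure(list(data = data, fs = fs, channel_labels = channel_labels,
                 events = events, truth = truth, config = config),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s), %d events\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs,
              nrow(x$events)))
  invisible(x)
}

empty_events <- function() {
  data.frame(onset_sample = integer(0), class = character(0),
             condition = character(0), stringsAsFactors = FALSE)
}

#' Number of samples in a recording
#' @param rec An `eeg_recording`.
#' @return Integer sample count.
#' @export
n_samples <- function(rec) ncol(rec$data)

#' Extract one channel of a recording
#' @param rec An `eeg_recording`.
#' @param channel Channel label.
#' @return Numeric vector of samples.
#' @export
get_channel <- function(rec, channel) {
  if (!channel %in% rec$channel_labels)
    stop(sprintf("channel '%s' not present in recording", channel))
  rec$data[channel, ]
}

# Gaussian smoothing by FFT convolution (circular; fine for long drifts).
smooth_gaussian <- function(x, sd_samples) {
  n <- length(x)
  f <- c(0:floor(n / 2), -(ceiling(n / 2) - 1):-1) / n
  g <- exp(-2 * (pi * f * sd_samples)^2)
  Re(stats::fft(stats::fft(x) * g, inverse = TRUE) / n)
}

# 1/f^a noise, unit variance, by spectral shaping of white noise.
one_over_f_noise <- function(n, fs, exponent, f_floor = 1) {
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  f <- seq(0, n - 1) / n * fs
  f <- pmin(f, fs - f)                    # two-sided frequency axis
  s <- pmax(f, f_floor)^(-exponent / 2)
  s[1] <- 0                               # drop DC
  x <- Re(stats::fft(W * s, inverse = TRUE) / n)
  x / stats::sd(x)
}

# A jittered narrowband alpha source: random-walk phase around a linear
# ramp at `freq`, slowly drifting positive envelope. The raw process has
# Lorentzian tails (Wiener phase noise is broadband), so the signal is
# band-limited to freq +/- 3 Hz with a zero-phase filter; `phase` is the
# driving (pre-filter) unwrapped sine-convention phase.
alpha_source <- function(n, fs, freq, phase_jitter_sd, envelope_drift_sd) {
  steps <- 2 * pi * freq / fs + stats::rnorm(n, 0, phase_jitter_sd)
  phase <- stats::runif(1, -pi, pi) + cumsum(steps)
  env <- exp(smooth_gaussian(stats::rnorm(n, 0, envelope_drift_sd), 0.5 * fs))
  env <- env / sqrt(mean(env^2))
  flt <- butter_bandpass(4, c(freq - 3, freq + 3), fs)
  list(phase = phase, envelope = env,
       signal = sos_filtfilt(flt, env * sin(phase)))
}

# Raised-cosine-edged gate: 1 inside [on, off) sample windows scaled by
# `depth_fun(t_rel)`, smooth 100 ms transitions.
erd_gate <- function(n, fs, onsets, win, depth, profile) {
  gate <- rep(1, n)
  ramp_len <- round(0.1 * fs)
  for (on in onsets) {
    a <- on + round(win[1] * fs) + 1      # 1-based task start
    b <- on + round(win[2] * fs)          # task end (inclusive)
    if (a > n) next
    b <- min(b, n)
    k <- seq(a, b)
    t_rel <- (k - a) / (b - a + 1)
    d <- if (profile == "ramp") depth * t_rel else rep(depth, length(k))
    mult <- 1 - d
    # smooth the edges so the injected change stays band-limited
    m <- length(k)
    e <- min(ramp_len, floor(m / 2))
    if (e > 1) {
      edge <- (1 - cos(pi * seq_len(e) / e)) / 2
      mult[seq_len(e)] <- 1 + (mult[seq_len(e)] - 1) * edge
      mult[seq(m, m - e + 1)] <- 1 + (mult[seq(m, m - e + 1)] - 1) * edge
    }
    gate[k] <- mult
  }
  gate
}

#' Generate a synthetic motor-imagery EEG session
#'
#' Produces a continuous multichannel recording with balanced MI / rest
#' trials. Every channel contains 1/f background noise; the sensorimotor
#' channels carry narrowband alpha sources (C4's at `alpha_freq`, C3's
#' offset by +0.5 Hz, a realistic inter-hemispheric peak difference that
#' also keeps the sources empirically uncorrelated); during the task
#' window of MI trials the C4 (contralateral) alpha envelope is multiplied
#' by `1 - erd_depth`. The two sources are spread over the montage by a
#' fixed random full-rank mixing (condition number capped at 100) drawn
#' from the seed.
#'
#' @param cfg A [synth_config()].
#' @param keep_truth Keep generator ground truth (source phases,
#'   envelopes, noiseless source signals, mixing matrix) in the returned
#'   object (default TRUE).
#' @return An [eeg_recording()] with an event table; `$truth` holds the
#'   ground truth when requested.
#' @export
#' @examples
#' rec <- generate_session(synth_config(n_trials = 2, seed = 7))
#' rec
generate_session <- function(cfg, keep_truth = TRUE) {
  stopifnot(inherits(cfg, "synth_config"))
  with_seed(cfg$seed, {
    fs <- cfg$fs
    n <- round(cfg$n_trials * cfg$trial_len * fs)
    nch <- cfg$n_channels
    labels <- cfg$channel_labels

    # balanced classes in random order
    half <- floor(cfg$n_trials / 2)
    classes <- sample(c(rep("MI", half), rep("rest", cfg$n_trials - half)))
    onsets <- round((seq_len(cfg$n_trials) - 1) * cfg$trial_len * fs)
    events <- data.frame(onset_sample = as.integer(onsets),
                         class = classes,
                         condition = cfg$condition,
                         stringsAsFactors = FALSE)

    snr_lin <- 10^(cfg$alpha_snr_db / 10)

    s4 <- alpha_source(n, fs, cfg$alpha_freq, cfg$phase_jitter_sd,
                       cfg$envelope_drift_sd)
    s3 <- alpha_source(n, fs, cfg$alpha_freq + 0.5, cfg$phase_jitter_sd,
                       cfg$envelope_drift_sd)

    # scale to the target in-channel SNR before applying ERD, so that
    # rest-trial alpha power sits exactly at snr_lin x noise power
    sc4 <- sqrt(snr_lin) / stats::sd(s4$signal)
    sc3 <- sqrt(snr_lin) / stats::sd(s3$signal)
    s4$signal <- s4$signal * sc4
    s4$envelope <- s4$envelope * sc4
    s3$signal <- s3$signal * sc3
    s3$envelope <- s3$envelope * sc3

    gate <- erd_gate(n, fs, onsets[classes == "MI"], cfg$task_window,
                     cfg$erd_depth, cfg$erd_profile)
    s4$signal <- s4$signal * gate
    s4$erd_gate <- gate

    # fixed random full-rank mixing, dominant weight on the home channel
    repeat {
      A <- matrix(stats::rnorm(nch * 2, 0, 0.15), nch, 2)
      A[match("C3", labels), 1] <- 1
      A[match("C4", labels), 2] <- 1
      A[match("C4", labels), 1] <- 0.1 * A[match("C4", labels), 1]
      A[match("C3", labels), 2] <- 0.1 * A[match("C3", labels), 2]
      sv <- svd(A)$d
      if (sv[1] / sv[length(sv)] <= 100) break
    }

    data <- A %*% rbind(s3$signal, s4$signal)
    for (ch in seq_len(nch)) {
      data[ch, ] <- data[ch, ] +
        one_over_f_noise(n, fs, cfg$noise_exponent)
    }
    rownames(data) <- labels

    truth <- NULL
    if (keep_truth) {
      truth <- list(
        C4 = s4, C3 = s3, mixing = A,
        alpha_freq = c(C3 = cfg$alpha_freq + 0.5, C4 = cfg$alpha_freq))
    }
    eeg_recording(data, fs, labels, events, truth = truth, config = cfg)
  })
}

#' Generate a pure sinusoid with known analytic phase
#'
#' Oracle input for tracker tests: `x(t) = sin(2 pi freq t + phase0)`, so
#' the sine-convention instantaneous phase is exactly
#' `2 pi freq t + phase0`.
#'
#' @param freq Frequency in Hz (must satisfy `0 < freq < fs / 2`).
#' @param fs Sampling rate in Hz.
#' @param duration Length in seconds; `round(duration * fs)` samples.
#' @param phase0 Initial phase in radians at `t = 0`.
#' @return Numeric vector of samples.
#' @export
#' @examples
#' x <- generate_pure_alpha(10, 1000, 1)
#' x[26]  # t = 0.025 s: sin(pi / 2) = 1
generate_pure_alpha <- function(freq, fs, duration, phase0 = 0) {
  if (freq <= 0 || freq >= fs / 2) stop("freq must lie in (0, fs/2)")
  t <- seq(0, by = 1 / fs, length.out = round(duration * fs))
  sin(2 * pi * freq * t + phase0)
}
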