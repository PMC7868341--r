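# Shared fixtures and independent oracle helpers. Everything is built in
# code at test time; sessions are kept small (a handful of trials) so the
# whole suite stays fast.

# A small synthetic session, memoised per parameter set within a test run.
local({
  cache <- new.env(parent = emptyenv())
  small_session <<- function(n_trials = 6, seed = 101, ...) {
    key <- paste(n_trials, seed, paste(deparse(list(...)), collapse = ""),
                 sep = "|")
    if (is.null(cache[[key]]))
      cache[[key]] <- generate_session(
        synth_config(n_trials = n_trials, seed = seed, ...))
    cache[[key]]
  }
})

# Independent phase wrap (different algorithm from wrap_phase: atan2).
wrap_oracle <- function(phi) atan2(sin(phi), cos(phi))

# Simple phase unwrap for oracle computations.
unwrap_for_test <- function(phi) {
  d <- diff(phi)
  corr <- cumsum(ifelse(d > pi, -2 * pi, ifelse(d < -pi, 2 * pi, 0)))
  c(phi[1], phi[-1] + corr)
}

# Independent interval membership on the unwrapped circle: walk from lo
# upwards in tiny steps until hi is reached; phi is a member if some step
# lands within eps of it (brute force, used to cross-check the wrap-aware
# predicate).
interval_member_bruteforce <- function(phi, lo, hi, n_grid = 1e5) {
  arc <- (hi - lo) %% (2 * pi)
  grid <- lo + seq(0, arc, length.out = n_grid)
  any(abs(wrap_oracle(grid - phi)) < (arc / n_grid + 1e-9))
}

# Mean alpha-band power of a signal segment by Welch-style averaging of
# Hann-windowed periodogram segments (independent of the package STFT).
welch_band_power <- function(x, fs, band, seg = 1 * fs) {
  starts <- seq(1, length(x) - seg + 1, by = seg %/% 2)
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(seg - 1)) / (seg - 1))
  ps <- sapply(starts, function(s) {
    X <- stats::fft(x[s:(s + seg - 1)] * w)
    f <- (seq_along(X) - 1) * fs / length(X)
    sel <- f >= band[1] & f <= band[2]
    sum(Mod(X[sel])^2)
  })
  mean(ps)
}

# Per-trial band power from a recording: task-window segment of one
# channel, Welch power in `band`.
trial_band_power <- function(rec, channel, band = c(8, 13),
                             window = c(5, 9)) {
  x <- get_channel(rec, channel)
  vapply(seq_len(nrow(rec$events)), function(k) {
    on <- rec$events$onset_sample[k]
    seg <- x[(on + window[1] * rec$fs + 1):(on + window[2] * rec$fs)]
    welch_band_power(seg, rec$fs, band)
  }, numeric(1))
}

# Hilbert ground-truth phase at given times (s) of a recording channel.
hilbert_at <- function(rec, channel, times, band = c(8, 12)) {
  ph <- hilbert_phase(get_channel(rec, channel), rec$fs, band)
  k <- round(times * rec$fs) + 1
  stopifnot(all(k >= 1), all(k <= length(ph)))
  ph[k]
}

# A dense noiseless phase-ramp estimate stream at frequency f.
ramp_estimates <- function(f = 10, t_end = 4, dt = 0.005) {
  t <- seq(0, t_end, by = dt)
  data.frame(t = t, phi = wrap_phase(2 * pi * f * t), f_dom = f, a_dom = 1)
}
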