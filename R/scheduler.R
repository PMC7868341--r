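# Phase-gated stimulus scheduling and stimulus waveform synthesis.
#
# Converts streaming phase estimates into 20 ms vibrotactile trigger
# events: a pulse fires when the predicted phase lies in the target
# interval (rising or falling flank of the alpha cycle), at least 100 ms
# after the previous pulse, with every third pulse 50% stronger
# ("tic-tic-toc" pattern). Also synthesizes the audio-rate waveforms: the
# 200 Hz pulse burst and the open-loop 23 Hz-modulated 200 Hz carrier.

#' A wrap-aware phase interval
#'
#' The interval is the arc traversed from `lo` to `hi` in increasing
#' phase; it may cross the +/-pi wrap point. Presets: the rising flank
#' `[-pi/6, pi/3]` brackets the ascending zero crossing and the falling
#' flank `[5 pi/6, 4 pi/3]` brackets the descending one (sine
#' convention).
#'
#' @param lo,hi Interval ends in radians (any real numbers; stored
#'   wrapped).
#' @return Object of class `phase_interval`.
#' @export
#' @examples
#' rising_interval()
#' phase_in_interval(0, rising_interval())
phase_interval <- function(lo, hi) {
  arc <- (hi - lo) %% (2 * pi)
  if (arc <= 0 || arc >= 2 * pi)
    stop("interval arc length must lie in (0, 2 pi)")
  structure(list(lo = wrap_phase(lo), hi = wrap_phase(hi), arc = arc),
            class = "phase_interval")
}

#' @rdname phase_interval
#' @export
rising_interval <- function() phase_interval(-pi / 6, pi / 3)

#' @rdname phase_interval
#' @export
falling_interval <- function() phase_interval(5 * pi / 6, 4 * pi / 3)

#' Test whether a phase lies on a phase interval's arc
#'
#' @param phi Phase in radians (wrapped or not).
#' @param iv A [phase_interval()].
#' @return Logical vector, TRUE where `phi` lies on the arc from `lo` to
#'   `hi` (inclusive ends); wrap points are handled.
#' @export
phase_in_interval <- function(phi, iv) {
  stopifnot(inherits(iv, "phase_interval"))
  ((phi - iv$lo) %% (2 * pi)) <= iv$arc
}

#' Schedule phase-gated stimulus events
#'
#' Walks the estimate stream in time order and emits a 20 ms trigger at
#' each estimate whose predicted phase lies in the target interval,
#' subject to a refractory period (consecutive onsets >= `refractory` ms
#' apart). Amplitude factors follow the tic-tic-toc pattern 1, 1, 1.5,
#' cycling over all emitted pulses (the counter is not reset between
#' alpha cycles or trials). When `task_windows` is supplied, pulses are
#' only emitted while the estimate's target time lies inside one of the
#' windows, matching a paradigm where stimulation runs only during the
#' task period of each trial.
#'
#' @param estimates A `phase_estimates` data frame (time-ordered).
#' @param iv Target [phase_interval()].
#' @param refractory Minimum onset-to-onset spacing in ms (default 100).
#' @param mode Condition label stored on the events (default `"FPS"`).
#' @param task_windows Optional 2-column matrix (start, end in seconds);
#'   pulses fire only inside these half-open windows.
#' @param duration Pulse duration in ms (default 20).
#' @return Data frame of class `stimulus_events`: `onset` (s),
#'   `duration` (ms), `amplitude_factor`, `mode`, `realized_phase` (NA
#'   until filled in by [realized_stimulus_phases()]).
#' @export
schedule <- function(estimates, iv, refractory = 100, mode = "FPS",
                     task_windows = NULL, duration = 20) {
  stopifnot(inherits(iv, "phase_interval"))
  est <- as.data.frame(estimates)
  if (nrow(est) > 1 && any(diff(est$t) < 0))
    stop("estimates must be time-ordered")
  gated <- if (nrow(est)) phase_in_interval(est$phi, iv) else logical(0)
  if (!is.null(task_windows) && nrow(est)) {
    task_windows <- matrix(task_windows, ncol = 2)
    inwin <- rep(FALSE, nrow(est))
    for (r in seq_len(nrow(task_windows))) {
      inwin <- inwin |
        (est$t >= task_windows[r, 1] & est$t < task_windows[r, 2])
    }
    gated <- gated & inwin
  }
  onsets <- numeric(0)
  last <- -Inf
  for (i in which(gated)) {
    if (est$t[i] - last >= refractory / 1000) {
      onsets <- c(onsets, est$t[i])
      last <- est$t[i]
    }
  }
  k <- seq_along(onsets)
  out <- data.frame(
    onset = onsets,
    duration = rep(duration, length(onsets)),
    amplitude_factor = ifelse(k %% 3 == 0, 1.5, 1.0),
    mode = rep(mode, length(onsets)),
    realized_phase = rep(NA_real_, length(onsets)))
  class(out) <- c("stimulus_events", "data.frame")
  attr(out, "interval") <- iv
  attr(out, "refractory") <- refractory
  out
}

# 2 ms raised-cosine on/off ramps; avoids clicks on real hardware and
# keeps the synthesized burst's spectrum clean.
edge_ramp <- function(n, fs_audio, ramp_ms = 2) {
  e <- max(2L, round(ramp_ms / 1000 * fs_audio))
  e <- min(e, floor(n / 2))
  ramp <- (1 - cos(pi * seq_len(e) / e)) / 2
  c(ramp, rep(1, n - 2 * e), rev(ramp))
}

#' Synthesize a single 200 Hz pulse burst
#'
#' @param duration Burst length in ms (default 20).
#' @param carrier Carrier frequency in Hz (default 200).
#' @param amplitude_factor Peak scaling (1.0 or 1.5 under the tic-tic-toc
#'   pattern).
#' @param fs_audio Audio sampling rate in Hz (default 8000).
#' @return Numeric waveform, `round(duration / 1000 * fs_audio)` samples.
#' @export
synthesize_pulse <- function(duration = 20, carrier = 200,
                             amplitude_factor = 1, fs_audio = 8000) {
  if (duration <= 0) stop("duration must be positive")
  n <- round(duration / 1000 * fs_audio)
  t <- (seq_len(n) - 1) / fs_audio
  amplitude_factor * sin(2 * pi * carrier * t) * edge_ramp(n, fs_audio)
}

#' Synthesize the open-loop continuous-vibration waveform
#'
#' Amplitude modulation of a 200 Hz carrier by a 23 Hz envelope,
#' `m(t) = (1 + sin(2 pi mod t)) / 2`, kept non-negative because a
#' voice-coil tactor follows the audio amplitude; the spectrum carries
#' lines at the carrier and at carrier +/- mod.
#'
#' @param duration Length in seconds.
#' @param mod Modulation frequency in Hz (default 23).
#' @param carrier Carrier frequency in Hz (default 200).
#' @param fs_audio Audio sampling rate in Hz (default 8000).
#' @return Numeric waveform.
#' @export
synthesize_cvs <- function(duration, mod = 23, carrier = 200,
                           fs_audio = 8000) {
  if (duration <= 0) stop("duration must be positive")
  n <- round(duration * fs_audio)
  t <- (seq_len(n) - 1) / fs_audio
  m <- (1 + sin(2 * pi * mod * t)) / 2
  m * sin(2 * pi * carrier * t)
}

#' Write stimulus events as delimited text
#'
#' @param events A `stimulus_events` data frame.
#' @param path Output file path (tab-separated).
#' @return Invisibly, the path.
#' @export
write_events <- function(events, path) {
  data.table::fwrite(as.data.frame(events), path, sep = "\t")
  invisible(path)
}
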