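# Offline ground truth and validation: Hilbert phase, phase-locking
# value, realized stimulus phases (rose-histogram data), trial rejection.

#' Offline instantaneous phase via the Hilbert analytic signal
#'
#' Zero-phase (forward-backward) bandpass followed by the analytic-signal
#' angle, converted to the package's sine convention (phase 0 at the
#' ascending zero crossing) and wrapped to [-pi, pi). The zero-phase
#' filter is deliberately different from the tracker's causal filter:
#' the oracle must not carry group delay.
#'
#' @param signal Numeric samples.
#' @param fs Sampling rate in Hz.
#' @param band Passband in Hz (default `c(8, 12)`).
#' @param order Bandpass order of the zero-phase elliptic filter
#'   (default 10).
#' @return Phase series in radians, same length as `signal`.
#' @export
#' @examples
#' x <- generate_pure_alpha(10, 1000, 2)
#' ph <- hilbert_phase(x, 1000)
#' ph[501]  # ~ wrap of 2 pi * 10 * 0.5
hilbert_phase <- function(signal, fs, band = c(8, 12), order = 10) {
  check_band(band, fs)
  if (length(signal) < 10 * order)
    stop("signal too short for stable zero-phase filtering")
  flt <- ellip_bandpass(order, band, fs)
  xb <- sos_filtfilt(flt, signal)
  wrap_phase(Arg(hilbert_analytic(xb)) + pi / 2)
}

#' Phase-locking value between two phase series
#'
#' `plv = |mean_k exp(i (phi_a[k] - phi_b[k]))|`; the argument of the same
#' mean is the circular mean phase error.
#'
#' @param phi_a,phi_b Phase series in radians, equal length, n >= 1.
#' @return Object of class `plv_report`: list with `plv` in [0, 1],
#'   `circ_mean_error` (rad) and `n`.
#' @export
plv <- function(phi_a, phi_b) {
  if (length(phi_a) != length(phi_b))
    stop("phase series must have equal length")
  if (length(phi_a) < 1) stop("need at least one sample")
  m <- mean(exp(1i * (phi_a - phi_b)))
  structure(list(plv = Mod(m), circ_mean_error = Arg(m),
                 n = length(phi_a)),
            class = "plv_report")
}

#' @export
print.plv_report <- function(x, ...) {
  cat(sprintf("PLV = %.3f (circular mean error %.3f rad, n = %d)\n",
              x$plv, x$circ_mean_error, x$n))
  invisible(x)
}

#' Realized phases of delivered stimuli and rose-histogram counts
#'
#' Fills each event's `realized_phase` with the offline Hilbert phase of
#' the target channel at the event onset, and bins the phases into a rose
#' histogram.
#'
#' @param events A `stimulus_events` data frame.
#' @param rec The [eeg_recording()] the events were scheduled on.
#' @param channel Channel whose phase defines the realized phase
#'   (default `"C4"`).
#' @param band Passband for the offline phase (default `c(8, 12)`).
#' @param n_bins Number of histogram bins over [-pi, pi) (default 18).
#' @return List of class `realized_phases`: `events` (with
#'   `realized_phase` filled), `histogram` (data frame: bin lo/hi/count),
#'   `circ_mean` (rad), `resultant` (mean vector length), `n`.
#' @export
realized_stimulus_phases <- function(events, rec, channel = "C4",
                                     band = c(8, 12), n_bins = 18) {
  stopifnot(inherits(rec, "eeg_recording"))
  events <- as.data.frame(events)
  breaks <- seq(-pi, pi, length.out = n_bins + 1)
  if (nrow(events) == 0) {
    hist <- data.frame(lo = breaks[-length(breaks)], hi = breaks[-1],
                       count = 0L)
    return(structure(list(events = events, histogram = hist,
                          circ_mean = NA_real_, resultant = NA_real_,
                          n = 0L),
                     class = "realized_phases"))
  }
  k <- round(events$onset * rec$fs) + 1       # onset 0 s -> sample 1
  if (any(k < 1) || any(k > n_samples(rec)))
    stop("event onset outside the recording")
  ph <- hilbert_phase(get_channel(rec, channel), rec$fs, band)
  events$realized_phase <- ph[k]
  counts <- table(cut(events$realized_phase, breaks,
                      include.lowest = TRUE, right = FALSE))
  hist <- data.frame(lo = breaks[-length(breaks)], hi = breaks[-1],
                     count = as.integer(counts))
  m <- mean(exp(1i * events$realized_phase))
  structure(list(events = events, histogram = hist,
                 circ_mean = Arg(m), resultant = Mod(m),
                 n = nrow(events)),
            class = "realized_phases")
}

#' @export
print.realized_phases <- function(x, ...) {
  cat(sprintf("%d stimuli; circular mean phase %.3f rad, resultant %.3f\n",
              x$n, x$circ_mean, x$resultant))
  invisible(x)
}

#' Flag trials with badly placed stimuli
#'
#' A trial is removed when the fraction of its pulses whose realized
#' phase falls outside the target interval exceeds `max_out_fraction`
#' (mirrors removing "trials with more errors in the applied stimulation
#' position"). Trials without any pulse are kept.
#'
#' @param events Events with `realized_phase` filled (a
#'   `realized_phases$events` data frame) plus a `trial` column, or a
#'   list of per-trial event data frames.
#' @param iv Target [phase_interval()].
#' @param max_out_fraction Rejection threshold on the out-of-interval
#'   fraction (default 0.5; the original criterion is unstated).
#' @return Data frame: `trial`, `n_pulses`, `out_fraction`, `keep`.
#' @export
flag_bad_trials <- function(events, iv, max_out_fraction = 0.5) {
  stopifnot(inherits(iv, "phase_interval"))
  if (is.data.frame(events)) {
    if (!"trial" %in% names(events))
      stop("events need a 'trial' column (or pass a per-trial list)")
    events <- split(events, events$trial)
  }
  res <- lapply(names(events), function(tr) {
    ev <- events[[tr]]
    n <- nrow(ev)
    out_frac <- if (n == 0) 0 else
      mean(!phase_in_interval(ev$realized_phase, iv))
    data.frame(trial = tr, n_pulses = n, out_fraction = out_frac,
               keep = out_frac <= max_out_fraction,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Attach trial indices to stimulus events
#'
#' Maps each event onset to the trial whose `[onset_sample,
#' onset_sample + trial_len)` span contains it.
#'
#' @param events A `stimulus_events` data frame.
#' @param rec An [eeg_recording()] with an event table.
#' @param trial_len Trial length in seconds.
#' @return The events with an integer `trial` column.
#' @export
assign_trials <- function(events, rec, trial_len) {
  events <- as.data.frame(events)
  starts <- rec$events$onset_sample / rec$fs
  idx <- findInterval(events$onset, starts)
  idx[events$onset - starts[pmax(idx, 1)] >= trial_len] <- NA
  events$trial <- idx
  events
}
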