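# Time-frequency analysis: trial-averaged ERSP, band ERD/ERS summaries,
# sliding band-energy time courses, and common-average re-referencing.

hann_window <- function(n) (1 - cos(2 * pi * (seq_len(n) - 1) / (n - 1))) / 2

# Short-time Fourier power of one epoch: returns freqs x times matrix of
# linear power, window centers in `times` (s, epoch-relative).
stft_power <- function(x, fs, win_n, hop_n, nfft, freq_idx) {
  starts <- seq(1, length(x) - win_n + 1, by = hop_n)
  w <- hann_window(win_n)
  M <- vapply(starts, function(s) x[s:(s + win_n - 1)] * w, numeric(win_n))
  X <- stats::mvfft(rbind(M, matrix(0, nfft - win_n, ncol(M))))
  P <- Mod(X[freq_idx, , drop = FALSE])^2
  list(P = P, times = (starts - 1 + (win_n - 1) / 2) / fs)
}

#' Trial-averaged event-related spectral perturbation (ERSP)
#'
#' Per-trial short-time Fourier power (Hann taper, 200 ms window),
#' averaged over trials (`ERSP(f, t) = mean_k |F_k(f, t)|^2`), converted
#' to dB, and baseline-normalized by subtracting each frequency's mean dB
#' level over the baseline window (log-ratio normalization; the baseline
#' mean of every frequency row is exactly 0 dB afterwards).
#'
#' @param trials Numeric matrix, trials x samples: single-channel epochs
#'   with a common time origin at the trial start.
#' @param fs Sampling rate in Hz.
#' @param win Analysis window length in ms (default 200).
#' @param hop STFT hop in ms (default 50).
#' @param baseline_window Baseline span in seconds (default `c(3, 4)`,
#'   the second before the attention cue).
#' @param freq_range Frequencies retained, in Hz (default `c(1, 30)`).
#' @param channel Channel label stored on the map (metadata only).
#' @param nfft FFT length; default gives a grid spacing <= 0.5 Hz.
#' @return Object of class `ersp_map`: `values` (freqs x times,
#'   baseline-normalized dB), `power` (the un-normalized linear
#'   trial-averaged power of Eq. form `mean_k |F_k|^2`), `freqs`,
#'   `times`, `channel`, `n_trials`, `baseline_window`.
#' @export
ersp <- function(trials, fs, win = 200, hop = 50,
                 baseline_window = c(3, 4), freq_range = c(1, 30),
                 channel = NA_character_, nfft = NULL) {
  trials <- as.matrix(trials)
  if (is.vector(trials)) trials <- matrix(trials, nrow = 1)
  n_trials <- nrow(trials)
  if (n_trials < 1) stop("need at least one trial")
  win_n <- round(win / 1000 * fs)
  hop_n <- max(1L, round(hop / 1000 * fs))
  if (ncol(trials) < win_n)
    stop("epoch shorter than the analysis window")
  if (is.null(nfft)) nfft <- max(2048L, 2^ceiling(log2(2 * fs)))
  freqs_all <- (seq_len(nfft) - 1) * fs / nfft
  freq_idx <- which(freqs_all >= freq_range[1] & freqs_all <= freq_range[2])
  acc <- NULL
  times <- NULL
  for (k in seq_len(n_trials)) {
    s <- stft_power(trials[k, ], fs, win_n, hop_n, nfft, freq_idx)
    acc <- if (is.null(acc)) s$P else acc + s$P
    times <- s$times
  }
  P <- acc / n_trials
  vals <- 10 * log10(pmax(P, .Machine$double.xmin))
  bl <- times >= baseline_window[1] & times <= baseline_window[2]
  if (!any(bl)) stop("baseline window contains no STFT frames")
  vals <- vals - rowMeans(vals[, bl, drop = FALSE])
  structure(list(values = vals, power = P, freqs = freqs_all[freq_idx],
                 times = times, channel = channel, n_trials = n_trials,
                 baseline_window = baseline_window),
            class = "ersp_map")
}

#' @export
print.ersp_map <- function(x, ...) {
  cat(sprintf("<ersp_map> %s: %d freqs (%.1f-%.1f Hz) x %d frames, %d trials\n",
              x$channel, length(x$freqs), min(x$freqs), max(x$freqs),
              length(x$times), x$n_trials))
  invisible(x)
}

#' Band-averaged ERD/ERS value from an ERSP map
#'
#' Mean of the map over a frequency band x time window rectangle;
#' negative values are desynchronization (ERD), positive are ERS.
#' Conventional presets: alpha 8-13 Hz, beta 14-30 Hz.
#'
#' @param map An [ersp()] result.
#' @param band Frequency band in Hz (default alpha, `c(8, 13)`).
#' @param window Time window in seconds (default `c(5, 9)`, the task).
#' @return Scalar dB value.
#' @export
band_erd <- function(map, band = c(8, 13), window = c(5, 9)) {
  stopifnot(inherits(map, "ersp_map"))
  fi <- map$freqs >= band[1] & map$freqs <= band[2]
  ti <- map$times >= window[1] & map$times <= window[2]
  if (!any(fi) || !any(ti)) stop("empty band/window selection")
  mean(map$values[fi, ti])
}

#' Sliding band-energy time course
#'
#' Average band power in a sliding window (1 s long, hopped 200 ms),
#' averaged over trials: the "energy fluctuation" view of ERD over the
#' task period.
#'
#' @param trials Trials x samples matrix of single-channel epochs.
#' @param fs Sampling rate in Hz.
#' @param band Band in Hz (default `c(8, 30)`, alpha-beta).
#' @param win Window length in s (default 1).
#' @param hop Hop in s (default 0.2).
#' @param span Portion of the epoch analyzed, in s (default `c(5, 9)`,
#'   the task window).
#' @param t_ref Time subtracted from window centers in the output
#'   (default `span[1]`, i.e. times are relative to task onset).
#' @param db Return dB (10 log10) instead of linear power (default
#'   FALSE).
#' @return Object of class `band_energy_curve`: `times` (s), `values`,
#'   `band`, `n_trials`.
#' @export
band_energy_curve <- function(trials, fs, band = c(8, 30), win = 1,
                              hop = 0.2, span = c(5, 9), t_ref = span[1],
                              db = FALSE) {
  trials <- as.matrix(trials)
  win_n <- round(win * fs)
  hop_n <- max(1L, round(hop * fs))
  a <- round(span[1] * fs) + 1
  b <- min(round(span[2] * fs), ncol(trials))
  if (b - a + 1 < win_n) stop("span shorter than the analysis window")
  starts <- seq(a, b - win_n + 1, by = hop_n)
  nfft <- 2^ceiling(log2(win_n))
  freqs <- (seq_len(nfft) - 1) * fs / nfft
  fi <- which(freqs >= band[1] & freqs <= band[2])
  w <- hann_window(win_n)
  vals <- vapply(starts, function(s) {
    seg <- trials[, s:(s + win_n - 1), drop = FALSE] *
      matrix(w, nrow(trials), win_n, byrow = TRUE)
    X <- stats::mvfft(t(cbind(seg, matrix(0, nrow(trials), nfft - win_n))))
    # total band energy (sum over bins): disjoint sub-bands add up to
    # the full band
    mean(colSums(Mod(X[fi, , drop = FALSE])^2))
  }, numeric(1))
  if (db) vals <- 10 * log10(vals)
  structure(list(times = (starts - 1 + (win_n - 1) / 2) / fs - t_ref,
                 values = vals, band = band, n_trials = nrow(trials),
                 db = db),
            class = "band_energy_curve")
}

#' Common average reference
#'
#' Subtracts the instantaneous mean over channels from every channel;
#' the output's per-sample channel mean is zero.
#'
#' @param rec An [eeg_recording()] (needs >= 2 channels).
#' @return The re-referenced recording.
#' @export
car_reference <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (nrow(rec$data) < 2)
    stop("common average reference needs at least 2 channels")
  rec$data <- sweep(rec$data, 2, colMeans(rec$data))
  rec
}

#' Extract single-channel trial epochs from a recording
#'
#' @param rec An [eeg_recording()] with an event table.
#' @param channel Channel label.
#' @param span Epoch span in seconds relative to trial onset (half-open;
#'   default `c(0, 9)`).
#' @param classes Optional subset of classes to keep.
#' @return List: `trials` (matrix trials x samples), `labels`
#'   (class per trial).
#' @export
epoch_channel <- function(rec, channel, span = c(0, 9), classes = NULL) {
  stopifnot(inherits(rec, "eeg_recording"))
  x <- get_channel(rec, channel)
  ev <- rec$events
  if (!is.null(classes)) ev <- ev[ev$class %in% classes, , drop = FALSE]
  if (nrow(ev) == 0) stop("no matching events")
  a_off <- round(span[1] * rec$fs)
  len <- round((span[2] - span[1]) * rec$fs)
  rows <- lapply(ev$onset_sample, function(on) {
    i0 <- on + a_off + 1
    if (i0 < 1 || i0 + len - 1 > length(x))
      stop("epoch extends outside the recording")
    x[i0:(i0 + len - 1)]
  })
  list(trials = do.call(rbind, rows), labels = ev$class)
}

#' Export an ERSP map as delimited text
#'
#' Tab-separated matrix with frequency row labels and time column
#' headers.
#'
#' @param map An [ersp()] result.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_ersp <- function(map, path) {
  df <- data.frame(freq_hz = map$freqs, round(map$values, 6))
  names(df)[-1] <- sprintf("t%.3f", map$times)
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}
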