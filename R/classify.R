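# Filter-bank common spatial patterns (FBCSP) with Fisher LDA and
# repeated stratified cross-validation.
#
# Six 4 Hz sub-bands spanning 8-32 Hz; per band, CSP spatial filters are
# fitted by joint diagonalization of the trace-normalized class
# covariances, log-variance features of the m most discriminative filter
# pairs are extracted, and a 2-class ridge-stabilized Fisher LDA is
# trained on the concatenated features. Cross-validation refits CSP and
# LDA on training folds only.

#' The default 8-32 Hz filter bank
#'
#' @param bandwidth Sub-band width in Hz (default 4).
#' @param range Overall range in Hz (default `c(8, 32)`).
#' @return List of length-2 band vectors.
#' @export
default_filter_bank <- function(bandwidth = 4, range = c(8, 32)) {
  lo <- seq(range[1], range[2] - bandwidth, by = bandwidth)
  lapply(lo, function(l) c(l, l + bandwidth))
}

#' Extract labeled multichannel epochs for classification
#'
#' Cuts, per trial, the all-channel segment from `window[1]` to
#' `window[2]` seconds after the imagery-task onset (task onset =
#' trial onset + `task_start`).
#'
#' @param rec An [eeg_recording()] with an event table.
#' @param window Epoch span in seconds relative to task onset, half-open
#'   (default `c(0.5, 4)`).
#' @param task_start Task onset within the trial, in s (default 5).
#' @return List of class `mi_epochs`: `epochs` (array channels x samples
#'   x trials), `labels` (character), `fs`, `channel_labels`.
#' @export
epoch_for_classification <- function(rec, window = c(0.5, 4),
                                     task_start = 5) {
  stopifnot(inherits(rec, "eeg_recording"))
  ev <- rec$events
  if (nrow(ev) == 0) stop("recording has no events")
  fs <- rec$fs
  a_off <- round((task_start + window[1]) * fs)
  len <- round((window[2] - window[1]) * fs)
  n_ch <- nrow(rec$data)
  arr <- array(NA_real_, c(n_ch, len, nrow(ev)))
  for (k in seq_len(nrow(ev))) {
    i0 <- ev$onset_sample[k] + a_off + 1
    if (i0 < 1 || i0 + len - 1 > ncol(rec$data))
      stop(sprintf("epoch for event %d extends outside the recording", k))
    arr[, , k] <- rec$data[, i0:(i0 + len - 1)]
  }
  structure(list(epochs = arr, labels = ev$class, fs = fs,
                 channel_labels = rec$channel_labels),
            class = "mi_epochs")
}

# Trace-normalized covariance of one channels x samples epoch.
trial_cov <- function(X) {
  C <- tcrossprod(X) / ncol(X)
  C / sum(diag(C))
}

# Zero-phase sub-band filtering of an epochs array; returns per-trial
# trace-normalized covariance matrices (channels x channels x trials).
# All trials and channels are filtered in one multivariate pass.
band_covariances <- function(epochs, fs, band, order = 4) {
  flt <- butter_bandpass(order, band, fs)
  d <- dim(epochs)
  n_ch <- d[1]; len <- d[2]; n_tr <- d[3]
  X <- matrix(aperm(epochs, c(2, 1, 3)), nrow = len)
  Y <- sos_filtfilt(flt, X, padlen = min(floor((len - 1) / 2), 500L))
  out <- array(NA_real_, c(n_ch, n_ch, n_tr))
  for (k in seq_len(n_tr)) {
    C <- crossprod(Y[, ((k - 1) * n_ch + 1):(k * n_ch), drop = FALSE]) / len
    out[, , k] <- C / sum(diag(C))
  }
  out
}

#' Fit common spatial patterns for one sub-band
#'
#' Averages trace-normalized per-trial covariances within each class,
#' whitens their sum, and eigendecomposes the whitened class-1
#' covariance. Filters are sorted by descending eigenvalue (class-1
#' variance ratio); the `m` first and `m` last filters form the
#' discriminative pairs. `W' (C1 + C2) W = I` holds by construction.
#'
#' @param covs Channels x channels x trials array of per-trial
#'   covariances (see also [csp_features()]), or an epochs array
#'   accompanied by `fs` and `band`.
#' @param labels Class label per trial (exactly 2 classes, >= 2 trials
#'   each).
#' @param m Number of filter pairs to retain (default 3).
#' @param reg Covariance shrinkage added when the composite covariance
#'   is near-singular (default 1e-8 of the average eigenvalue; the
#'   fallback is reported via a warning).
#' @param fs,band When `covs` is a raw epochs array: sampling rate and
#'   sub-band for zero-phase filtering before covariance estimation.
#' @return Object of class `csp_model`: `filters` (channels x 2m),
#'   `w_full`, `eigenvalues`, `selected`, `classes`, `band`.
#' @export
fit_csp <- function(covs, labels, m = 3, reg = 1e-8, fs = NULL,
                    band = NULL) {
  if (length(dim(covs)) == 3 && !is.null(fs) && !is.null(band) &&
      dim(covs)[1] != dim(covs)[2]) {
    covs <- band_covariances(covs, fs, band)
  }
  classes <- sort(unique(labels))
  if (length(classes) != 2) stop("CSP needs exactly 2 classes")
  if (min(table(labels)) < 2) stop("need >= 2 trials per class")
  n_ch <- dim(covs)[1]
  C1 <- apply(covs[, , labels == classes[1], drop = FALSE], c(1, 2), mean)
  C2 <- apply(covs[, , labels == classes[2], drop = FALSE], c(1, 2), mean)
  Cc <- C1 + C2
  e <- eigen(Cc, symmetric = TRUE)
  # whiten within the signal subspace: numerically null directions (e.g.
  # the direction removed by common-average referencing) are dropped
  tol <- max(e$values) * 1e-10
  keep <- e$values > tol
  r <- sum(keep)
  if (r < 2 * m) {
    warning("severely rank-deficient composite covariance; applying shrinkage")
    Cc <- Cc + diag(reg * mean(diag(Cc)) + tol, n_ch)
    e <- eigen(Cc, symmetric = TRUE)
    keep <- rep(TRUE, n_ch)
    r <- n_ch
  }
  P <- e$vectors[, keep, drop = FALSE] %*% diag(1 / sqrt(e$values[keep]), r)
  S1 <- crossprod(P, C1 %*% P)
  es <- eigen((S1 + t(S1)) / 2, symmetric = TRUE)
  W <- P %*% es$vectors                        # columns: spatial filters
  m <- min(m, floor(r / 2))
  sel <- c(seq_len(m), seq(r - m + 1, r))
  structure(list(filters = W[, sel, drop = FALSE], w_full = W,
                 eigenvalues = es$values, selected = sel, rank = r,
                 classes = classes, band = band, m = m),
            class = "csp_model")
}

#' Log-variance CSP features of one epoch
#'
#' Per retained spatial filter, the log of its share of the filtered
#' variance: `log(var_j / sum_j var_j)`. The normalization makes the
#' features invariant to a global scaling of the epoch.
#'
#' @param epoch Channels x samples matrix, or a channels x channels
#'   covariance matrix of the (already sub-band filtered) epoch.
#' @param model A fitted [fit_csp()] model.
#' @return Numeric feature vector of length `2 m`.
#' @export
csp_features <- function(epoch, model) {
  if (!inherits(model, "csp_model")) stop("model must be a fitted csp_model")
  W <- model$filters
  C <- if (nrow(epoch) == ncol(epoch) && isSymmetric(unname(epoch)))
    epoch else tcrossprod(epoch) / ncol(epoch)
  v <- diag(t(W) %*% C %*% W)
  log(v / sum(v))
}

# ---- Fisher LDA (2-class, ridge-stabilized pooled covariance) ----------

fit_lda <- function(X, y, ridge = 1e-6) {
  classes <- sort(unique(y))
  stopifnot(length(classes) == 2)
  X1 <- X[y == classes[1], , drop = FALSE]
  X2 <- X[y == classes[2], , drop = FALSE]
  mu1 <- colMeans(X1); mu2 <- colMeans(X2)
  Sw <- (crossprod(sweep(X1, 2, mu1)) + crossprod(sweep(X2, 2, mu2))) /
    (nrow(X) - 2)
  Sw <- Sw + diag(ridge * mean(diag(Sw)), ncol(X))
  w <- solve(Sw, mu1 - mu2)
  b <- -sum(w * (mu1 + mu2)) / 2
  list(w = w, b = b, classes = classes)
}

predict_lda <- function(model, X) {
  s <- drop(X %*% model$w) + model$b
  ifelse(s > 0, model$classes[1], model$classes[2])
}

# Stratified fold assignment: within each class, trials are shuffled and
# dealt round-robin into `folds` groups.
stratified_folds <- function(labels, folds) {
  assign <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    assign[idx] <- rep_len(seq_len(folds), length(idx))
  }
  assign
}

#' Repeated cross-validated FBCSP + LDA accuracy
#'
#' 10 x 10-fold stratified cross-validation of the full pipeline:
#' per training fold, CSP filters are fitted per sub-band and an LDA is
#' trained on the concatenated log-variance features; the held-out fold
#' is scored with those models only (no leakage). Per-trial sub-band
#' covariances are precomputed once (sub-band filtering does not depend
#' on the fold split), which keeps the 100 fits cheap.
#'
#' @param epochs An `mi_epochs` object (see
#'   [epoch_for_classification()]).
#' @param bank Filter bank (default [default_filter_bank()]).
#' @param m CSP pairs per band (default 3).
#' @param repeats,folds Cross-validation shape (default 10 x 10).
#' @param seed Master seed; per-repeat fold seeds derive from it.
#' @param sub_band_order Zero-phase Butterworth order per sub-band
#'   (default 4).
#' @return Object of class `cv_report`: `fold_accuracies`
#'   (repeats x folds values), `mean_accuracy`, `repeat_means`,
#'   `n_trials`, `bank`, `m`.
#' @export
crossvalidate <- function(epochs, bank = default_filter_bank(), m = 3,
                          repeats = 10, folds = 10, seed = 1,
                          sub_band_order = 4) {
  stopifnot(inherits(epochs, "mi_epochs"))
  labels <- epochs$labels
  n_tr <- length(labels)
  if (n_tr < 20) stop("need at least 20 trials")
  if (min(table(labels)) < folds)
    stop("each class needs at least one trial per fold")
  covs <- lapply(bank, function(b)
    band_covariances(epochs$epochs, epochs$fs, b, order = sub_band_order))

  acc <- matrix(NA_real_, repeats, folds)
  for (r in seq_len(repeats)) {
    fold_of <- with_seed(derive_seed(seed, r),
                         stratified_folds(labels, folds))
    for (f in seq_len(folds)) {
      test <- which(fold_of == f)
      train <- which(fold_of != f)
      feats <- matrix(NA_real_, n_tr, 0)
      for (bi in seq_along(bank)) {
        mod <- fit_csp(covs[[bi]][, , train, drop = FALSE],
                       labels[train], m = m, band = bank[[bi]])
        fb <- t(vapply(seq_len(n_tr), function(k)
          csp_features(covs[[bi]][, , k], mod), numeric(2 * mod$m)))
        feats <- cbind(feats, fb)
      }
      lda <- fit_lda(feats[train, , drop = FALSE], labels[train])
      pred <- predict_lda(lda, feats[test, , drop = FALSE])
      acc[r, f] <- mean(pred == labels[test])
    }
  }
  structure(list(fold_accuracies = as.numeric(t(acc)),
                 mean_accuracy = mean(acc),
                 repeat_means = rowMeans(acc),
                 n_trials = n_tr, bank = bank, m = m,
                 repeats = repeats, folds = folds),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("%d x %d-fold CV: mean accuracy %.3f (sd over folds %.3f), %d trials\n",
              x$repeats, x$folds, x$mean_accuracy,
              stats::sd(x$fold_accuracies), x$n_trials))
  invisible(x)
}
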