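# ERSP, band summaries, band-energy curves, CAR.

test_that("stationary white noise gives a ~0 dB ERSP", {
  set.seed(8)
  wn <- matrix(rnorm(50 * 9000), 50)
  m <- ersp(wn, 1000)
  # per-pixel estimates are chi-square noise around 0 dB (sd ~ 0.7 dB
  # at 50 trials); band averages sit within 1 dB of zero
  expect_gt(mean(abs(m$values) < 2), 0.98)
  expect_lt(abs(mean(m$values)), 0.5)
  expect_lt(abs(band_erd(m, c(8, 13), c(5, 9))), 1)
  expect_lt(abs(band_erd(m, c(14, 30), c(5, 9))), 1)
})

test_that("50% alpha-power ERD appears as ~ -6 dB at the alpha peak", {
  cfg <- synth_config(n_trials = 20, alpha_snr_db = 30, erd_depth = 0.5,
                      seed = 5)
  rec <- generate_session(cfg, keep_truth = FALSE)
  ep <- epoch_channel(rec, "C4", span = c(0, 9), classes = "MI")
  m <- ersp(ep$trials, rec$fs, channel = "C4")
  val <- band_erd(m, band = c(9, 11), window = c(5.5, 8.5))
  expect_equal(val, 10 * log10(0.25), tolerance = 1)
})

test_that("beta band stays flat under alpha ERD at moderate SNR", {
  cfg <- synth_config(n_trials = 16, alpha_snr_db = 10, erd_depth = 0.5,
                      seed = 9)
  rec <- generate_session(cfg, keep_truth = FALSE)
  ep <- epoch_channel(rec, "C4", span = c(0, 9), classes = "MI")
  m <- ersp(ep$trials, rec$fs, channel = "C4")
  expect_lt(band_erd(m, band = c(9, 11), window = c(5.5, 8.5)), -3)
  # far beta band (clear of the 200 ms Hann mainlobe/near sidelobes of
  # the strong alpha line) stays flat
  expect_lt(abs(band_erd(m, band = c(20, 30), window = c(5.5, 8.5))), 1)
})

test_that("single-trial ERSP equals the trial's normalized spectrogram", {
  set.seed(2)
  x <- rnorm(9000)
  m1 <- ersp(matrix(x, 1), 1000)
  expect_equal(m1$n_trials, 1)
  # recompute by hand for one (freq, time) cell
  m2 <- ersp(rbind(x, x), 1000)
  expect_equal(m1$values, m2$values, tolerance = 1e-9)
})

test_that("baseline row means are exactly zero after normalization", {
  set.seed(3)
  m <- ersp(matrix(rnorm(5 * 9000), 5), 1000)
  bl <- m$times >= 3 & m$times <= 4
  expect_lt(max(abs(rowMeans(m$values[, bl]))), 1e-6)
})

test_that("ERSP is linear in trial sets pre-dB and gain-invariant post-dB", {
  set.seed(13)
  t1 <- matrix(rnorm(6 * 9000), 6)
  t2 <- matrix(rnorm(4 * 9000), 4)
  ma <- ersp(rbind(t1, t2), 1000)
  m1 <- ersp(t1, 1000)
  m2 <- ersp(t2, 1000)
  # Eq.-1 linearity of the trial-averaged linear power
  expect_equal(ma$power, (6 * m1$power + 4 * m2$power) / 10,
               tolerance = 1e-9)
  # baseline normalization cancels any constant gain
  mg <- ersp(3.7 * rbind(t1, t2), 1000)
  expect_equal(mg$values, ma$values, tolerance = 1e-9)
})

test_that("band_erd averages the selected rectangle", {
  m <- ersp(matrix(rnorm(2 * 9000), 2), 1000)
  m$values[] <- 0
  expect_equal(band_erd(m, c(8, 13), c(5, 9)), 0)
  fi <- m$freqs >= 8 & m$freqs <= 13
  ti <- m$times >= 5 & m$times <= 9
  m$values[fi, ti] <- -3
  expect_equal(band_erd(m, c(8, 13), c(5, 9)), -3)
  expect_error(band_erd(m, c(50, 60), c(5, 9)), "empty")
})

test_that("band-energy curve is flat for stationary input", {
  set.seed(21)
  tr <- matrix(rnorm(25 * 9000), 25)
  cur <- band_energy_curve(tr, 1000)
  expect_equal(diff(cur$times), rep(0.2, length(cur$times) - 1),
               tolerance = 1e-9)
  expect_lt(diff(range(cur$values)) / mean(cur$values), 0.2)
})

test_that("ramped ERD yields a monotonically decreasing energy curve", {
  cfg <- synth_config(n_trials = 16, erd_depth = 0.7, erd_profile = "ramp",
                      alpha_snr_db = 15, seed = 37)
  rec <- generate_session(cfg, keep_truth = FALSE)
  ep <- epoch_channel(rec, "C4", span = c(0, 11), classes = "MI")
  cur <- band_energy_curve(ep$trials, rec$fs)
  rho <- stats::cor(cur$times, cur$values, method = "spearman")
  expect_lt(rho, -0.9)
  # rest trials stay near their baseline power
  epr <- epoch_channel(rec, "C4", span = c(0, 11), classes = "rest")
  curr <- band_energy_curve(epr$trials, rec$fs)
  base <- band_energy_curve(epr$trials, rec$fs, span = c(1, 5),
                            t_ref = 1)
  expect_lt(abs(mean(curr$values) - mean(base$values)) /
            mean(base$values), 0.1)
})

test_that("sub-band partition energies sum to the full band", {
  set.seed(31)
  tr <- matrix(rnorm(6 * 9000), 6)
  full <- band_energy_curve(tr, 1000, band = c(8, 30))
  # sub-band edges offset off the FFT grid so no bin is counted twice
  edges <- c(8, 13.1, 18.3, 24.7, 30)
  parts <- lapply(seq_len(4), function(i)
    band_energy_curve(tr, 1000, band = c(edges[i], edges[i + 1])))
  partsum <- Reduce(`+`, lapply(parts, `[[`, "values"))
  expect_equal(partsum, full$values, tolerance = 0.02)
})

test_that("car_reference removes the common mode", {
  rec <- small_session(n_trials = 2, seed = 3)
  out <- car_reference(rec)
  expect_lt(max(abs(colMeans(out$data))), 1e-10)
  # already zero-mean pair is unchanged
  x <- rnorm(500)
  rec2 <- eeg_recording(rbind(C3 = x, C4 = -x), 1000, c("C3", "C4"))
  expect_equal(car_reference(rec2)$data, rec2$data)
  # common offset is rejected
  rec3 <- rec
  rec3$data <- rec$data + matrix(5, nrow(rec$data), ncol(rec$data))
  expect_equal(car_reference(rec3)$data, out$data)
  one <- eeg_recording(matrix(rnorm(100), 1), 1000, "C4")
  expect_error(car_reference(one), "2 channels")
})
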