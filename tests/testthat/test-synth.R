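# Synthetic-session generator: determinism, injected effect sizes,
# component bookkeeping, band-limitation of the injected ERD.

test_that("configuration invariants are enforced", {
  expect_error(synth_config(erd_depth = 1), "erd_depth")
  expect_error(synth_config(erd_depth = -0.1), "erd_depth")
  expect_error(synth_config(task_window = c(5, 12)), "task_window")
  expect_error(synth_config(n_channels = 5), "montage|channel")
  expect_error(synth_config(channel_labels = rep("C3", 27)), "unique")
  expect_error(
    synth_config(channel_labels = c(paste0("X", 1:27)), n_channels = 27),
    "C3")
})

test_that("identical config yields bit-identical sessions", {
  cfg <- synth_config(n_trials = 2, seed = 42)
  r1 <- generate_session(cfg)
  r2 <- generate_session(cfg)
  expect_identical(r1$data, r2$data)
  expect_identical(r1$events, r2$events)
  # a different seed changes the data
  r3 <- generate_session(synth_config(n_trials = 2, seed = 43))
  expect_false(identical(r1$data, r3$data))
})

test_that("session structure matches the paradigm", {
  rec <- small_session(n_trials = 4, seed = 7)
  expect_s3_class(rec, "eeg_recording")
  expect_equal(nrow(rec$data), 27)
  expect_equal(ncol(rec$data), 4 * 11 * 1000)
  expect_true(all(c("C3", "C4") %in% rec$channel_labels))
  expect_equal(nrow(rec$events), 4)
  expect_equal(sort(unique(rec$events$class)), c("MI", "rest"))
  expect_true(all(rec$events$onset_sample + 11 * 1000 <= ncol(rec$data)))
})

test_that("ERD scales contralateral alpha power by (1 - depth)^2", {
  # closed form on the noiseless alpha component: amplitude x (1 - d)
  # during MI task windows => Welch band power ratio (1 - d)^2 = 0.25
  cfg <- synth_config(n_trials = 12, erd_depth = 0.5, alpha_snr_db = 10,
                      seed = 31)
  rec <- generate_session(cfg)
  alpha <- rec$truth$C4$signal
  fs <- rec$fs
  p <- vapply(seq_len(nrow(rec$events)), function(k) {
    on <- rec$events$onset_sample[k]
    welch_band_power(alpha[(on + 5 * fs + 1):(on + 9 * fs)], fs, c(8, 13))
  }, numeric(1))
  ratio <- mean(p[rec$events$class == "MI"]) /
    mean(p[rec$events$class == "rest"])
  expect_equal(ratio, 0.25, tolerance = 0.2)
})

test_that("erd_depth = 0 leaves MI and rest statistically identical", {
  # alpha log-power two-sample test, alpha = 0.01: with no injected
  # effect it should fail to reject on >= 9 of 10 seeds
  rejections <- vapply(1:10, function(s) {
    rec <- generate_session(synth_config(n_trials = 8, erd_depth = 0,
                                         seed = 300 + s))
    p <- log(trial_band_power(rec, "C4"))
    stats::t.test(p[rec$events$class == "MI"],
                  p[rec$events$class == "rest"])$p.value < 0.01
  }, logical(1))
  expect_gte(sum(!rejections), 9)
})

test_that("channel variance decomposes into component variances", {
  cfg <- synth_config(n_trials = 8, seed = 17)
  rec <- generate_session(cfg)
  A <- rec$truth$mixing
  i4 <- match("C4", rec$channel_labels)
  mixed <- A[i4, 1] * rec$truth$C3$signal + A[i4, 2] * rec$truth$C4$signal
  noise_var <- stats::var(rec$data[i4, ] - mixed)
  expect_equal(stats::var(rec$data[i4, ]),
               A[i4, 1]^2 * stats::var(rec$truth$C3$signal) +
               A[i4, 2]^2 * stats::var(rec$truth$C4$signal) + noise_var,
               tolerance = 0.01)
  # the in-channel alpha SNR is close to the configured 10 dB
  snr_db <- 10 * log10(stats::var(rec$truth$C4$signal *
                                  A[i4, 2]) / noise_var)
  expect_equal(snr_db, 10, tolerance = 1.5)
})

test_that("ERD injection is band-limited", {
  # same seed with and without ERD shares every random draw, so the
  # per-trial difference isolates exactly what the injection changed
  rec1 <- generate_session(synth_config(n_trials = 12, erd_depth = 0.6,
                                        seed = 53))
  rec0 <- generate_session(synth_config(n_trials = 12, erd_depth = 0,
                                        seed = 53))
  expect_identical(rec1$events, rec0$events)
  mi <- rec1$events$class == "MI"
  hi1 <- trial_band_power(rec1, "C4", band = c(30, 45))
  hi0 <- trial_band_power(rec0, "C4", band = c(30, 45))
  expect_lt(max(abs(hi1 - hi0) / hi0), 0.05)
  al1 <- trial_band_power(rec1, "C4")
  al0 <- trial_band_power(rec0, "C4")
  expect_lt(mean(al1[mi]) / mean(al0[mi]), 0.7)   # alpha did drop
  expect_equal(al1[!mi], al0[!mi], tolerance = 1e-10)  # rest untouched
})

test_that("pure alpha oracle signal has exact phase structure", {
  x <- generate_pure_alpha(10, 1000, 1, phase0 = 0)
  expect_length(x, 1000)
  expect_equal(x[26], sin(pi / 2), tolerance = 1e-12)  # t = 0.025 s
  expect_equal(generate_pure_alpha(10, 1000, 1, phase0 = pi), -x,
               tolerance = 1e-12)
  # Hilbert instantaneous frequency of the interior ~ 10 Hz
  a <- hilbert_analytic(generate_pure_alpha(10, 1000, 4))
  instf <- diff(unwrap_for_test(Arg(a))) * 1000 / (2 * pi)
  expect_equal(mean(instf[500:3400]), 10, tolerance = 0.01)
  expect_error(generate_pure_alpha(600, 1000, 1), "fs/2")
})
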