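sine_rec <- function(freqs, rate = 1000, dur = 4, amp = 1) {
  tt <- seq(0, dur - 1 / rate, by = 1 / rate)
  signal_recording(lapply(freqs, function(f) amp * sin(2 * pi * f * tt)),
                   rate)
}

test_that("notch removes 50 Hz, preserves 10 Hz, and is linear", {
  rec <- sine_rec(c(50, 10, 0))
  out <- notch_filter(rec, 50)
  mid <- 1001:3000                       # avoid edge transients
  rms <- function(x) sqrt(mean(x^2))
  expect_lt(rms(out$data[1, mid]) / rms(rec$data[1, mid]), 0.03)
  expect_lt(abs(rms(out$data[2, mid]) / rms(rec$data[2, mid]) - 1), 0.01)
  expect_equal(out$data[3, ], rep(0, ncol(rec$data)))
  scaled <- rec; scaled$data <- 3.7 * scaled$data
  expect_equal(notch_filter(scaled, 50)$data, 3.7 * out$data,
               tolerance = 1e-10)
  expect_error(notch_filter(rec, 600), "Nyquist")
})

test_that("Butterworth band edges behave per the analytic response", {
  rec <- sine_rec(c(10, 50))
  bp <- butterworth_filter(rec, low = 8, high = 13)
  mid <- 1001:3000
  amp <- function(x) sqrt(2 * mean(x^2))
  expect_lt(abs(amp(bp$data[1, mid]) - 1), 0.05)   # 10 Hz inside 8-13
  lp <- butterworth_filter(rec, high = 3)
  atten_db <- 20 * log10(amp(lp$data[2, mid]))
  expect_lt(atten_db, -40)                          # 50 Hz through 3 Hz LP
  expect_error(butterworth_filter(rec), "at least one")
  expect_error(butterworth_filter(rec, high = 800), "Nyquist")
})

test_that("zero-phase filtering leaves the sinusoid peak time unchanged", {
  rate <- 1000
  tt <- seq(0, 4 - 1 / rate, by = 1 / rate)
  rec <- signal_recording(list(cos(2 * pi * 5 * (tt - 2))), rate)
  out <- butterworth_filter(rec, low = 2, high = 10)
  mid <- 1901:2100                       # one cycle around the t = 2 s peak
  peak_in <- mid[which.max(rec$data[1, mid])]
  peak_out <- mid[which.max(out$data[1, mid])]
  expect_lte(abs(peak_in - peak_out), 1)
})

test_that("resampling preserves waveform, duration, and event times", {
  rate <- 1000
  tt <- seq(0, 4 - 1 / rate, by = 1 / rate)
  ev <- data.frame(sample = c(500L, 1000L, 2000L),
                   code = c("TRIAL_START", "KEY_LEFT", "KEY_LEFT"),
                   task = c("LL", NA, NA))
  rec <- signal_recording(list(sin(2 * pi * 5 * tt)), rate, events = ev)
  r200 <- resample_to(rec, 200)
  t2 <- seq(0, by = 1 / 200, length.out = ncol(r200$data))
  expect_gt(stats::cor(r200$data[1, ], sin(2 * pi * 5 * t2)), 0.999)
  r16 <- resample_to(rec, 16)
  expect_lt(abs(ncol(r16$data) / 16 - ncol(rec$data) / rate), 1 / 16)
  expect_equal(r16$events$sample, c(8L, 16L, 32L))  # 1 s -> sample 16
  expect_error(resample_to(rec, 2000), "upsampling")
})

test_that("CAR zeroes the channel mean and removes common-mode signal", {
  set.seed(1)
  rec <- signal_recording(lapply(1:4, function(i) rnorm(500)), 250)
  out <- common_average_reference(rec)
  expect_lt(max(abs(colMeans(out$data))), 1e-12)
  expect_equal(out$reference, "CAR")
  # invariance to adding any common-mode signal
  common <- sin(seq_len(500) / 10)
  shifted <- rec
  shifted$data <- sweep(rec$data, 2, -common)
  expect_equal(common_average_reference(shifted)$data, out$data,
               tolerance = 1e-12)
  # unit impulse on one of N channels -> 1 - 1/N vs -1/N
  imp <- signal_recording(list(c(1, 0), c(0, 0), c(0, 0), c(0, 0)), 100)
  ci <- common_average_reference(imp)
  expect_equal(unname(ci$data[, 1]), c(1 - 1/4, -1/4, -1/4, -1/4))
  one <- signal_recording(list(rnorm(10)), 100)
  expect_error(common_average_reference(one), "2 channels")
})

test_that("behavioural rejection applies the wrong-key and 2 s rules", {
  rate <- 100
  ev <- rbind(trial_events(0, "LL", 2, 3, rate),      # conforming, gap 1 s
              trial_events(6, "LL", 8, 10.5, rate),   # gap 2.5 s -> late
              trial_events(13, "LR", 15, 16, rate))   # will get wrong keys
  ev$code[8:9] <- c("KEY_RIGHT", "KEY_LEFT")          # LR pressed as RL
  mont <- mini_montage()
  rec <- eeg_recording(matrix(0, length(mont), 1800), rate, mont, ev)
  res <- reject_bad_trials(rec)
  expect_equal(res$kept, 1L)
  expect_equal(res$dropped$reason, c("late_key", "wrong_key"))
  # malformed trial: only one key event
  ev2 <- rbind(trial_events(0, "RR", 2, 3, rate)[1:2, ])
  rec2 <- eeg_recording(matrix(0, length(mont), 500), rate, mont, ev2)
  expect_equal(reject_bad_trials(rec2)$dropped$reason, "malformed")
})

test_that("rejection recovers exactly the injected bad-trial list", {
  rec <- clean_dataset(trials_per_block = 20, seed = 13)
  bad <- inject_bad_trials(rec, 0.25, seed = 7)
  res <- reject_bad_trials(bad)
  expect_equal(res$dropped$trial, attr(bad, "bad_trials"))
  expect_equal(sort(c(res$kept, res$dropped$trial)), 1:20)
  kept_rec <- keep_trials(bad, res$kept)
  expect_equal(length(split_trials(kept_rec$events)), length(res$kept))
})

test_that("ICA isolates an injected blink source and can leave data alone", {
  sched <- make_protocol(n_blocks = 1, trials_per_block = 12, seed = 21)
  p <- signal_params(eog_rate = 12, eog_amp = 120)
  rec <- simulate_dataset(sched, p, mini_montage(), rate = 250, seed = 22)
  blink <- attr(rec, "truth")$blink_course
  res <- ica_artifact_removal(rec, n_components = 10,
                              eog_reference = blink, threshold = 0.8,
                              seed = 5)
  expect_gte(length(res$decomposition$removed), 1)
  best <- max(abs(apply(res$decomposition$sources, 1, stats::cor, y = blink)))
  expect_gt(best, 0.9)
  # unmixing is a left inverse of mixing on the retained subspace
  prod <- res$decomposition$unmixing %*% res$decomposition$mixing
  expect_equal(prod, diag(nrow(prod)), tolerance = 1e-6)
  # unreachable threshold: nothing removed, signal untouched
  noop <- ica_artifact_removal(rec, n_components = 10,
                               eog_reference = blink, threshold = 1.0,
                               seed = 5)
  expect_length(noop$decomposition$removed, 0)
  expect_equal(noop$rec$data, rec$data, tolerance = 1e-9)
  expect_error(ica_artifact_removal(rec, n_components = 10,
                                    criterion = "eog_correlation"),
               "eog_reference")
})
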