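# Small montage covering the sensorimotor and frontal rows; keeps the
# simulator and eigen-solvers fast in unit tests.
mini_montage <- function() {
  labs <- c("FP1", "FPZ", "FP2", "F3", "FZ", "F4",
            "C5", "C3", "C1", "CZ", "C2", "C4", "C6",
            "P3", "PZ", "P4", "O1", "O2")
  montage(labs, t(vapply(labs, seqfinger:::position_1020, numeric(2))))
}

# Recording holding given channel signals (list of numeric vectors).
signal_recording <- function(signals, rate, events = NULL) {
  n_ch <- length(signals)
  labs <- c("C3", "CZ", "C4", "F3", "FZ", "F4", "P3", "PZ", "P4")[seq_len(n_ch)]
  mont <- montage(labs, t(vapply(labs, seqfinger:::position_1020, numeric(2))))
  ev <- if (is.null(events)) seqfinger:::empty_events() else events
  eeg_recording(do.call(rbind, signals), rate, mont, ev)
}

# Zero-noise simulated dataset on the mini montage.
clean_dataset <- function(n_blocks = 1, trials_per_block = 8, seed = 1,
                          rate = 250, jitter_sd = 0, ...) {
  p <- signal_params(noise_scale = 0, line_amp = 0, eog_rate = 0, ...)
  sched <- make_protocol(n_blocks = n_blocks,
                         trials_per_block = trials_per_block,
                         seed = seed, jitter_sd = jitter_sd)
  simulate_dataset(sched, p, mini_montage(), rate = rate, seed = seed + 1)
}

# Noisy simulated dataset on the mini montage.
noisy_dataset <- function(n_blocks = 1, trials_per_block = 16, seed = 1,
                          rate = 250, ...) {
  sched <- make_protocol(n_blocks = n_blocks,
                         trials_per_block = trials_per_block, seed = seed)
  simulate_dataset(sched, signal_params(...), mini_montage(), rate = rate,
                   seed = seed + 1)
}

# dense brute-force generalized eigendecomposition oracle
brute_geigen <- function(A, B) {
  e <- eigen(solve(B, A))
  ord <- order(Re(e$values), decreasing = TRUE)
  list(values = Re(e$values[ord]), vectors = Re(e$vectors[, ord]))
}

random_spd <- function(n, seed) {
  set.seed(seed)
  M <- matrix(rnorm(n * n), n)
  crossprod(M) + diag(n) * 0.1
}

# epochs with a stationary or step-modulated rhythm plus white noise,
# built directly on the 200 Hz ERSP grid; freq defaults to an STFT bin
# centre so the rhythm occupies one bin exactly
make_tf_epochs <- function(n_trials, step_gain = 1, noise_sd = 0.3,
                           seed = 1, tmin = -2.14, tmax = 3.14,
                           freq = 200 * 13 / 256) {
  set.seed(seed)
  rate <- 200
  n <- round((tmax - tmin) * rate)
  tt <- tmin + (seq_len(n) - 1) / rate
  gain <- ifelse(tt >= 0, step_gain, 1)
  dat <- array(0, dim = c(n_trials, 3, n))
  for (i in seq_len(n_trials)) {
    phase <- stats::runif(1, 0, 2 * pi)
    osc <- gain * cos(2 * pi * freq * tt + phase)
    for (ch in 1:3)
      dat[i, ch, ] <- osc + stats::rnorm(n, sd = noise_sd)
  }
  eeg_epochs(dat, rep("LL", n_trials), tmin, tmax, rate, c("C3", "CZ", "C4"))
}

# events table for one well-formed trial
trial_events <- function(start, task, key1, key2, rate) {
  fingers <- c(substr(task, 1, 1), substr(task, 2, 2))
  code <- ifelse(fingers == "L", "KEY_LEFT", "KEY_RIGHT")
  data.frame(sample = round(c(start, key1, key2) * rate),
             code = c("TRIAL_START", code),
             task = c(task, NA, NA), stringsAsFactors = FALSE)
}
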