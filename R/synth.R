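#' Signal-model parameters for the synthetic EEG generator
#'
#' Defaults describe a plausible sequential-keystroke EEG: a
#' Bereitschaftspotential-like negative ramp peaking at each keystroke with
#' contralateral dominance (left finger loads C4-side channels, right finger
#' C3-side), ongoing alpha/beta rhythms over sensorimotor cortex whose
#' amplitude drops (ERD) around each keystroke, pink background noise,
#' 50 Hz line interference, and optional frontal blink artifacts.
#'
#' @param mrcp_peak_amp MRCP peak amplitude in microvolts (<= 0).
#' @param mrcp_rise_start seconds before a keystroke at which the negative
#'   ramp begins.
#' @param mrcp_rebound seconds of half-cosine return to baseline after the
#'   peak.
#' @param mrcp_second_scale amplitude factor for the second keystroke of
#'   repeated-finger tasks (LL, RR); the non-initial press of a rehearsed
#'   repeat is weaker.
#' @param contralateral_ratio contralateral/ipsilateral gain ratio (>= 1).
#' @param erd_alpha_depth,erd_beta_depth fractional amplitude attenuation of
#'   the alpha/beta rhythm inside the movement window, in `[0, 1]`.
#' @param erd_window numeric length-2, seconds around each keystroke over
#'   which ERD applies.
#' @param alpha_freq,beta_freq rhythm frequencies in Hz.
#' @param alpha_amp,beta_amp baseline rhythm amplitudes in microvolts.
#' @param noise_scale standard deviation of the 1/f background, microvolts.
#' @param line_amp 50 Hz line interference amplitude, microvolts.
#' @param eog_rate blink rate in blinks/minute (0 disables).
#' @param eog_amp blink peak amplitude at the forehead, microvolts.
#' @param spatial_spread decay constant (montage distance units) of the
#'   Gaussian scalp kernels used for all spatial weighting.
#' @return named list of validated parameters (`signal_params` class).
#' @export
signal_params <- function(mrcp_peak_amp = -8, mrcp_rise_start = 1.5,
                          mrcp_rebound = 0.5, mrcp_second_scale = 0.8,
                          contralateral_ratio = 2,
                          erd_alpha_depth = 0.5, erd_beta_depth = 0.4,
                          erd_window = c(-0.5, 0.5),
                          alpha_freq = 10, beta_freq = 20,
                          alpha_amp = 5, beta_amp = 3,
                          noise_scale = 6, line_amp = 2,
                          eog_rate = 2, eog_amp = 100,
                          spatial_spread = 0.35) {
  p <- as.list(environment())
  if (p$mrcp_peak_amp > 0) stop("mrcp_peak_amp must be <= 0 (a negativity)")
  for (f in c("erd_alpha_depth", "erd_beta_depth"))
    if (p[[f]] < 0 || p[[f]] > 1) stop(f, " must lie in [0, 1]")
  for (f in c("contralateral_ratio", "alpha_amp", "beta_amp", "noise_scale",
              "line_amp", "eog_rate", "eog_amp", "spatial_spread",
              "mrcp_rise_start", "mrcp_rebound"))
    if (p[[f]] < 0) stop(f, " must be >= 0")
  if (p$contralateral_ratio < 1) stop("contralateral_ratio must be >= 1")
  if (diff(p$erd_window) <= 0) stop("erd_window must have positive length")
  structure(p, class = "signal_params")
}

task_fingers <- function(task) {
  c(substr(task, 1, 1), substr(task, 2, 2)) # "L"/"R" per keystroke
}

finger_code <- function(finger) {
  if (finger == "L") "KEY_LEFT" else "KEY_RIGHT"
}

#' Balanced offline protocol schedule
#'
#' Builds the offline session timeline: per block, each task occurs the same
#' number of times in seeded random order. Each trial has a 1 s ready cue,
#' a self-paced first keystroke, a second keystroke ~1 s later and a 2 s
#' rest before the next trial.
#'
#' @param n_blocks number of blocks (default 10).
#' @param trials_per_block trials per block (default 60), must be divisible
#'   by the number of tasks.
#' @param tasks task label set.
#' @param seed integer seed driving all ordering and timing randomness.
#' @param jitter_sd standard deviation (s) of the keystroke-2 timing jitter,
#'   truncated at `jitter_max`.
#' @param jitter_max truncation bound (s) for the jitter.
#' @param react_range range (s) of the uniform delay between the end of the
#'   ready cue and the first keystroke.
#' @param key_interval nominal keystroke-1 to keystroke-2 interval (s).
#' @return data.frame (`block`, `trial`, `task`, `cue`, `key1`, `key2`,
#'   `end`), times in seconds from the schedule origin.
#' @export
make_protocol <- function(n_blocks = 10, trials_per_block = 60,
                          tasks = TASKS, seed = 1,
                          jitter_sd = 0.05, jitter_max = 0.15,
                          react_range = c(1.2, 2.0), key_interval = 1.0) {
  if (trials_per_block %% length(tasks) != 0)
    stop("trials_per_block (", trials_per_block,
         ") must be divisible by the number of tasks (", length(tasks), ")")
  set.seed(seed)
  per <- trials_per_block / length(tasks)
  blocks <- lapply(seq_len(n_blocks), function(b)
    sample(rep(tasks, per)))
  schedule_from_tasks(unlist(blocks), rep(seq_len(n_blocks),
                                          each = trials_per_block),
                      jitter_sd, jitter_max, react_range, key_interval)
}

schedule_from_tasks <- function(task_seq, block_seq, jitter_sd, jitter_max,
                                react_range, key_interval) {
  n <- length(task_seq)
  react <- stats::runif(n, react_range[1], react_range[2])
  jit <- if (jitter_sd > 0) {
    j <- stats::rnorm(n, 0, jitter_sd)
    pmin(pmax(j, -jitter_max), jitter_max)
  } else rep(0, n)
  cue <- numeric(n); key1 <- numeric(n); key2 <- numeric(n); tend <- numeric(n)
  t <- 0
  for (i in seq_len(n)) {
    cue[i] <- t
    key1[i] <- cue[i] + 1 + react[i]      # 1 s ready cue, then self-paced
    key2[i] <- key1[i] + key_interval + jit[i]
    tend[i] <- key2[i] + 2                # 2 s rest
    t <- tend[i]
  }
  data.frame(block = block_seq, trial = seq_len(n), task = task_seq,
             cue = cue, key1 = key1, key2 = key2, end = tend,
             stringsAsFactors = FALSE)
}

#' Online protocol schedule
#'
#' Blocks 1-6 mirror the offline structure (60 trials each, all four tasks
#' balanced: 360 trials, 90 per task). Block 7 holds 40 trials (20 LL,
#' 20 RR, shuffled); block 8 holds 40 trials (20 LR, 20 RL, shuffled).
#'
#' @inheritParams make_protocol
#' @return schedule data.frame as in [make_protocol()].
#' @export
make_online_protocol <- function(seed = 1, jitter_sd = 0.05,
                                 jitter_max = 0.15,
                                 react_range = c(1.2, 2.0),
                                 key_interval = 1.0) {
  set.seed(seed)
  train <- lapply(1:6, function(b) sample(rep(TASKS, 15)))
  b7 <- sample(rep(c("LL", "RR"), 20))
  b8 <- sample(rep(c("LR", "RL"), 20))
  task_seq <- c(unlist(train), b7, b8)
  block_seq <- c(rep(1:6, each = 60), rep(7L, 40), rep(8L, 40))
  schedule_from_tasks(task_seq, block_seq, jitter_sd, jitter_max,
                      react_range, key_interval)
}

# Gaussian scalp kernel centred on a channel, by montage distance.
scalp_kernel <- function(mont, center, spread) {
  d <- montage_distances(mont)[, channel_index(mont, center)]
  exp(-d^2 / (2 * spread^2))
}

# Spatial gain for one finger's movement-related activity: contralateral
# hand knob dominant (left finger -> C4), ipsilateral down-weighted.
finger_gain <- function(finger, params, mont) {
  contra <- if (finger == "L") "C4" else "C3"
  ipsi <- if (finger == "L") "C3" else "C4"
  scalp_kernel(mont, contra, params$spatial_spread) +
    scalp_kernel(mont, ipsi, params$spatial_spread) / params$contralateral_ratio
}

# MRCP temporal profile (unit peak) around a keystroke at time 0: linear
# negative ramp over [-rise, 0], half-cosine rebound over [0, rebound].
mrcp_profile <- function(t, rise, rebound) {
  y <- numeric(length(t))
  up <- t >= -rise & t < 0
  y[up] <- 1 + t[up] / rise
  dn <- t >= 0 & t < rebound
  y[dn] <- 0.5 * (1 + cos(pi * t[dn] / rebound))
  y
}

# ERD amplitude-modulation factor for one band at one channel set:
# 1 - depth * gain inside the window around each keystroke (max reduction
# where windows overlap). `t` is relative to key1; k2 = key2 - key1.
erd_modulation <- function(t, k2, depth, window, gain) {
  in1 <- t >= window[1] & t < window[2]
  in2 <- (t - k2) >= window[1] & (t - k2) < window[2]
  red <- outer(gain, as.numeric(in1 | in2)) * depth  # ch x time
  1 - red
}

# Deterministic per-trial signal (channels x length(t)) for one task;
# t is time relative to the first keystroke, k2 the key2 offset (s).
trial_signal <- function(task, t, k2, params, mont) {
  fingers <- task_fingers(task)
  n_ch <- length(mont)
  sig <- matrix(0, n_ch, length(t))
  key_t <- c(0, k2)
  for (k in 1:2) {
    amp <- params$mrcp_peak_amp
    if (k == 2 && fingers[1] == fingers[2]) amp <- amp * params$mrcp_second_scale
    prof <- mrcp_profile(t - key_t[k], params$mrcp_rise_start,
                         params$mrcp_rebound)
    sig <- sig + (finger_gain(fingers[k], params, mont) * amp) %o% prof
  }
  # ongoing rhythms, phase-locked to key1, amplitude-modulated by ERD
  base <- scalp_kernel(mont, "C3", params$spatial_spread) +
    scalp_kernel(mont, "C4", params$spatial_spread)
  for (band in list(list(f = params$alpha_freq, a = params$alpha_amp,
                         d = params$erd_alpha_depth),
                    list(f = params$beta_freq, a = params$beta_amp,
                         d = params$erd_beta_depth))) {
    if (band$a == 0) next
    carrier <- cos(2 * pi * band$f * t)
    # ERD is contralaterally weighted per keystroke; combine both keys
    mod <- matrix(1, n_ch, length(t))
    for (k in 1:2) {
      g <- finger_gain(fingers[k], params, mont)
      g <- g / max(g)
      m <- erd_modulation(t - key_t[k] + 0, 0, band$d, params$erd_window, g)
      # erd_modulation handles one key when k2 = 0; take elementwise min
      mod <- pmin(mod, m)
    }
    sig <- sig + (band$a * base) * mod * rep(carrier, each = n_ch)
  }
  sig
}

#' Deterministic class template
#'
#' The noise-free signal a single trial of `task` contributes inside an
#' epoch window, with the first keystroke at time 0 and the second exactly
#' `key_interval` later (snapped to the sample grid). With noise, line and
#' blinks disabled and zero timing jitter, epoch averages from
#' [simulate_dataset()] equal this template exactly.
#'
#' @param task one of LL/RR/LR/RL.
#' @param params [signal_params()].
#' @param mont a [montage].
#' @param rate sampling rate, Hz.
#' @param tmin,tmax window in seconds, half-open.
#' @param key_interval keystroke spacing in seconds.
#' @return channels x samples matrix, microvolts.
#' @export
class_template <- function(task, params, mont, rate, tmin = -2, tmax = 3,
                           key_interval = 1.0) {
  n <- round((tmax - tmin) * rate)
  t <- tmin + (seq_len(n) - 1) / rate
  k2 <- round(key_interval * rate) / rate
  trial_signal(task, t, k2, params, mont)
}

# Pink (1/f-amplitude) noise, unit variance, via FFT shaping.
pink_noise <- function(n) {
  m <- stats::nextn(n)
  x <- stats::rnorm(m)
  X <- stats::fft(x)
  f <- c(1, seq_len(m - 1))          # DC guarded
  f <- pmin(f, m - f + 1)            # symmetric frequency index
  X <- X / sqrt(pmax(f, 2))
  y <- Re(stats::fft(X, inverse = TRUE))[seq_len(n)]
  (y - mean(y)) / stats::sd(y)
}

#' Simulate a continuous EEG recording for a schedule
#'
#' Renders the deterministic task signal of every trial (MRCP ramps with
#' contralateral dominance, ERD-modulated alpha/beta rhythms) onto a
#' continuous timeline, then adds spatially mixed 1/f background noise,
#' 50 Hz line interference and, optionally, frontal blink artifacts.
#' Keystroke times are snapped to the sample grid before rendering so the
#' zero-noise class template identity is exact. Events are emitted for every
#' cue (TRIAL_START with the task) and keystroke (KEY_LEFT/KEY_RIGHT).
#'
#' @param schedule protocol data.frame from [make_protocol()] /
#'   [make_online_protocol()].
#' @param params [signal_params()].
#' @param mont a [montage] containing C3, Cz, C4.
#' @param rate sampling rate in Hz; must exceed twice the beta frequency.
#' @param seed integer seed for the noise and artifact randomness.
#' @param pad lead-in/tail seconds of signal-free recording.
#' @return an [eeg_recording]; attribute `truth` holds the schedule (with
#'   snapped key times) and the blink time course.
#' @export
simulate_dataset <- function(schedule, params = signal_params(),
                             mont = standard_montage_60(), rate = 1000,
                             seed = 1, pad = 4) {
  require_sensorimotor(mont)
  if (rate < 2 * params$beta_freq)
    stop("rate ", rate, " Hz cannot represent the beta rhythm (need >= ",
         2 * params$beta_freq, " Hz)")
  set.seed(seed)
  n_ch <- length(mont)
  offset <- pad                                 # schedule origin in seconds
  n <- ceiling((max(schedule$end) + offset + pad) * rate)
  data <- matrix(0, n_ch, n)

  snap <- function(s) round((s + offset) * rate) / rate - offset
  sched <- schedule
  sched$key1 <- snap(sched$key1)
  sched$key2 <- snap(sched$key2)

  # trial spans partition the timeline; the boundary sits 2.2 s after each
  # trial's (snapped) second keystroke — inside the rest period, so every
  # trial's widest epoch window stays within its own span. Lead-in goes to
  # trial 1, tail to the last trial. 0-based, non-overlapping.
  n_tr <- nrow(sched)
  bounds <- c(0, pmin(round((sched$key2[-n_tr] + 2.2 + offset) * rate), n), n)
  for (i in seq_len(nrow(sched))) {
    i0 <- bounds[i]
    i1 <- bounds[i + 1] - 1
    t <- (i0:i1) / rate - (sched$key1[i] + offset)
    k2 <- sched$key2[i] - sched$key1[i]
    data[, (i0:i1) + 1] <- data[, (i0:i1) + 1] +
      trial_signal(sched$task[i], t, k2, params, mont)
  }

  tt <- (seq_len(n) - 1) / rate
  if (params$noise_scale > 0) {
    n_src <- 20
    src <- vapply(seq_len(n_src), function(i) pink_noise(n), numeric(n))
    mix <- matrix(stats::rnorm(n_ch * n_src), n_ch, n_src)
    mix <- mix / sqrt(rowSums(mix^2))
    data <- data + params$noise_scale *
      (0.9 * mix %*% t(src) +
         0.45 * matrix(stats::rnorm(n_ch * n), n_ch, n))
  }
  if (params$line_amp > 0)
    data <- data + rep(params$line_amp, n_ch) %o% sin(2 * pi * 50 * tt)

  blink_course <- numeric(n)
  if (params$eog_rate > 0) {
    n_blinks <- stats::rpois(1, params$eog_rate * n / rate / 60)
    if (n_blinks > 0) {
      centers <- sort(stats::runif(n_blinks, 0.5, n / rate - 0.5))
      for (b in centers)
        blink_course <- blink_course + exp(-(tt - b)^2 / (2 * 0.08^2))
      front_ch <- mont$names[which.max(mont$positions[, 2])]
      frontal <- scalp_kernel(mont, front_ch, params$spatial_spread * 1.2)
      data <- data + (params$eog_amp * frontal) %o% blink_course
    }
  }

  ev <- do.call(rbind, lapply(seq_len(nrow(sched)), function(i) {
    fingers <- task_fingers(sched$task[i])
    data.frame(
      sample = c(round((sched$cue[i] + offset) * rate),
                 round((sched$key1[i] + offset) * rate),
                 round((sched$key2[i] + offset) * rate)),
      code = c("TRIAL_START", finger_code(fingers[1]),
               finger_code(fingers[2])),
      task = c(sched$task[i], NA, NA), stringsAsFactors = FALSE)
  }))
  rec <- eeg_recording(data, rate, mont, ev, reference = "nose")
  attr(rec, "truth") <- list(schedule = sched, offset = offset,
                             blink_course = blink_course)
  rec
}

#' Inject behavioural violations into a recording's events
#'
#' Marks a seeded random subset of trials bad by either flipping a key code
#' (contradicting the task) or delaying the second keystroke beyond the 2 s
#' rejection bound. Only the event stream is altered; the signal is left in
#' place, which suffices for testing the behavioural rejection rule.
#'
#' @param rec an [eeg_recording] with trials.
#' @param fraction fraction of trials to corrupt, in `[0, 1)`.
#' @param seed integer seed.
#' @return the recording with modified events; attributes `bad_trials`
#'   (sorted indices) and `bad_reasons` give the ground truth.
#' @export
inject_bad_trials <- function(rec, fraction, seed = 1) {
  if (fraction < 0 || fraction >= 1) stop("fraction must lie in [0, 1)")
  trials <- split_trials(rec$events)
  n <- length(trials)
  n_bad <- round(fraction * n)
  if (n_bad == 0) {
    attr(rec, "bad_trials") <- integer(0)
    attr(rec, "bad_reasons") <- character(0)
    return(rec)
  }
  set.seed(seed)
  bad <- sort(sample(n, n_bad))
  mode <- sample(c("wrong_key", "late_key"), n_bad, replace = TRUE)
  ev <- rec$events
  n_total <- ncol(rec$data)
  for (j in seq_along(bad)) {
    tr <- trials[[bad[j]]]
    keys <- which(ev$sample %in% tr$sample &
                    ev$code %in% c("KEY_LEFT", "KEY_RIGHT"))
    keys <- keys[ev$sample[keys] >= tr$sample[1]][1:2]
    if (mode[j] == "wrong_key") {
      k <- keys[sample(2, 1)]
      ev$code[k] <- setdiff(c("KEY_LEFT", "KEY_RIGHT"), ev$code[k])
    } else {
      gap <- stats::runif(1, 2.2, 2.6)
      new_s <- ev$sample[keys[1]] + round(gap * rec$rate)
      if (new_s >= n_total) { # fall back to a wrong key at the boundary
        ev$code[keys[2]] <- setdiff(c("KEY_LEFT", "KEY_RIGHT"),
                                    ev$code[keys[2]])
        mode[j] <- "wrong_key"
      } else {
        ev$sample[keys[2]] <- new_s
      }
    }
  }
  ord <- order(ev$sample)
  rec$events <- validate_events(ev[ord, ], n_total)
  attr(rec, "bad_trials") <- bad
  attr(rec, "bad_reasons") <- mode
  rec
}
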