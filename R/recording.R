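#' Continuous multi-channel EEG recording
#'
#' The central container for continuous data: a channels x samples matrix in
#' microvolts with a sampling rate, a [montage], an event table and a
#' reference label. Event `sample` indices are 0-based (sample 0 is t = 0 s),
#' so `time = sample / rate`; they are converted to 1-based indices only when
#' slicing the data matrix.
#'
#' @param data numeric matrix, channels x samples, microvolts. Row order is
#'   montage order.
#' @param rate sampling rate in Hz (> 0).
#' @param montage a [montage]; `nrow(data)` must equal its size.
#' @param events data.frame with columns `sample` (0-based integer), `code`
#'   (one of TRIAL_START, KEY_LEFT, KEY_RIGHT) and `task` (LL/RR/LR/RL on
#'   TRIAL_START rows, NA otherwise), sorted by sample.
#' @param reference reference label, e.g. "nose" or "CAR".
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, rate, montage, events = empty_events(),
                          reference = "nose") {
  data <- as.matrix(data)
  if (!is.numeric(data)) stop("data must be numeric")
  if (nrow(data) != length(montage))
    stop("data has ", nrow(data), " rows but montage has ", length(montage),
         " channels")
  if (!is.numeric(rate) || length(rate) != 1 || rate <= 0)
    stop("rate must be a single positive number")
  events <- validate_events(events, n_samples = ncol(data))
  rownames(data) <- montage$names
  structure(list(data = data, rate = rate, montage = montage,
                 events = events, reference = reference),
            class = "eeg_recording")
}

EVENT_CODES <- c("TRIAL_START", "KEY_LEFT", "KEY_RIGHT")

#' @export
print.eeg_recording <- function(x, ...) {
  cat("<eeg_recording> ", nrow(x$data), " ch x ", ncol(x$data), " samples @ ",
      x$rate, " Hz (", round(ncol(x$data) / x$rate, 1), " s), ",
      nrow(x$events), " events, reference ", x$reference, "\n", sep = "")
  invisible(x)
}

empty_events <- function() {
  data.frame(sample = integer(0), code = character(0), task = character(0),
             stringsAsFactors = FALSE)
}

validate_events <- function(events, n_samples) {
  events <- as.data.frame(events)
  need <- c("sample", "code", "task")
  if (!all(need %in% names(events)))
    stop("events must have columns: ", paste(need, collapse = ", "))
  events <- events[, need]
  if (nrow(events) == 0) return(empty_events())
  events$sample <- as.integer(events$sample)
  events$code <- as.character(events$code)
  events$task <- as.character(events$task)
  if (any(is.na(events$sample)) || any(events$sample < 0))
    stop("event samples must be non-negative integers")
  if (any(events$sample >= n_samples))
    stop("event at sample ", max(events$sample),
         " beyond recording length (", n_samples, " samples)")
  if (is.unsorted(events$sample))
    stop("events must be sorted by sample")
  bad <- setdiff(unique(events$code), EVENT_CODES)
  if (length(bad)) stop("unknown event codes: ", paste(bad, collapse = ", "))
  ts <- events$code == "TRIAL_START"
  if (any(ts & (is.na(events$task) | !events$task %in% TASKS)))
    stop("TRIAL_START events must carry a task in ", paste(TASKS, collapse = "/"))
  events$task[!ts] <- NA_character_
  rownames(events) <- NULL
  events
}

#' Split an event table into trials
#'
#' Trials run from one TRIAL_START to the next; any key events before the
#' first TRIAL_START are ignored.
#'
#' @param events event table as in [eeg_recording].
#' @return list of data.frames, one per trial (first row TRIAL_START).
#' @export
split_trials <- function(events) {
  starts <- which(events$code == "TRIAL_START")
  if (length(starts) == 0) return(list())
  ends <- c(starts[-1] - 1, nrow(events))
  lapply(seq_along(starts), function(i) {
    tr <- events[starts[i]:ends[i], , drop = FALSE]
    rownames(tr) <- NULL
    tr
  })
}

#' Epoched EEG (trials x channels x samples)
#'
#' Fixed windows cut around an anchor event, time 0 at the anchor. Windows
#' use the half-open convention `[tmin, tmax)`, so an epoch holds exactly
#' `round((tmax - tmin) * rate)` samples regardless of rate.
#'
#' @param data numeric array trials x channels x samples.
#' @param labels per-trial task labels (LL/RR/LR/RL).
#' @param tmin,tmax window bounds in seconds relative to the anchor.
#' @param rate sampling rate in Hz.
#' @param channels channel names (montage order).
#' @return An object of class `eeg_epochs`.
#' @export
eeg_epochs <- function(data, labels, tmin, tmax, rate, channels) {
  data <- as.array(data)
  if (length(dim(data)) != 3) stop("epoch data must be a 3-d array")
  n_expect <- round((tmax - tmin) * rate)
  if (dim(data)[3] != n_expect)
    stop("epoch sample count ", dim(data)[3], " != round((tmax-tmin)*rate) = ",
         n_expect)
  if (length(labels) != dim(data)[1])
    stop("labels length must equal trial count")
  if (length(channels) != dim(data)[2])
    stop("channels length must equal channel dimension")
  structure(list(data = data, labels = as.character(labels),
                 tmin = tmin, tmax = tmax, rate = rate,
                 channels = as.character(channels)),
            class = "eeg_epochs")
}

#' @export
print.eeg_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat("<eeg_epochs> ", d[1], " trials x ", d[2], " ch x ", d[3],
      " samples @ ", x$rate, " Hz, window [", x$tmin, ", ", x$tmax, ") s\n",
      sep = "")
  invisible(x)
}

#' Time axis of an epoch set
#' @param epochs an [eeg_epochs].
#' @return numeric vector of sample times in seconds (anchor at 0).
#' @export
epoch_times <- function(epochs) {
  epochs$tmin + (seq_len(dim(epochs$data)[3]) - 1) / epochs$rate
}

#' Cut epochs around each trial's anchor event
#'
#' One epoch is extracted per trial, time-locked to the anchor (by default
#' the first key event of the trial); the trial's task label is copied from
#' its TRIAL_START event. Trials whose window would leave the recording are
#' dropped with a warning, never silently.
#'
#' @param rec an [eeg_recording] with events.
#' @param tmin,tmax epoch window in seconds, half-open `[tmin, tmax)`.
#' @param anchor `"first_key"` (default), `"second_key"` or `"trial_start"`.
#' @return An [eeg_epochs]; attribute `dropped` lists dropped trial indices.
#' @export
extract_epochs <- function(rec, tmin, tmax, anchor = c("first_key",
                                                       "second_key",
                                                       "trial_start")) {
  anchor <- match.arg(anchor)
  if (tmin >= tmax) stop("tmin must be < tmax")
  trials <- split_trials(rec$events)
  if (length(trials) == 0) stop("recording has no trials")
  n_samp <- round((tmax - tmin) * rec$rate)
  offset <- round(tmin * rec$rate)
  n_total <- ncol(rec$data)

  anchors <- vapply(trials, function(tr) {
    keys <- tr$sample[tr$code %in% c("KEY_LEFT", "KEY_RIGHT")]
    switch(anchor,
           first_key = if (length(keys) >= 1) keys[1] else NA_integer_,
           second_key = if (length(keys) >= 2) keys[2] else NA_integer_,
           trial_start = tr$sample[1])
  }, integer(1))
  labels <- vapply(trials, function(tr) tr$task[1], character(1))

  start <- anchors + offset          # 0-based start sample of the window
  ok <- !is.na(anchors) & start >= 0 & (start + n_samp) <= n_total
  dropped <- which(!ok)
  if (length(dropped))
    warning(length(dropped), " trial(s) dropped (window outside recording ",
            "or missing anchor): ", paste(dropped, collapse = ", "))
  if (!any(ok)) stop("no trial window fits inside the recording")

  keep <- which(ok)
  arr <- array(0, dim = c(length(keep), nrow(rec$data), n_samp))
  for (i in seq_along(keep)) {
    s0 <- start[keep[i]] + 1          # to 1-based matrix index
    arr[i, , ] <- rec$data[, s0:(s0 + n_samp - 1)]
  }
  ep <- eeg_epochs(arr, labels[keep], tmin, tmax, rec$rate,
                   rec$montage$names)
  attr(ep, "dropped") <- dropped
  attr(ep, "trial_index") <- keep
  ep
}
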