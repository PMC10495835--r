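#' Behavioural trial rejection
#'
#' A trial is dropped iff its key presses contradict the task's expected
#' finger sequence ("wrong_key"), its two keystrokes are separated by more
#' than 2 s ("late_key"), or it does not contain exactly two key events
#' ("malformed"). Every rejection carries its reason.
#'
#' @param rec an [eeg_recording] with trial events.
#' @param max_gap maximum allowed keystroke separation in seconds.
#' @return list with `kept` (trial indices), `dropped` (data.frame `trial`,
#'   `task`, `reason`).
#' @export
reject_bad_trials <- function(rec, max_gap = 2) {
  trials <- split_trials(rec$events)
  if (length(trials) == 0) stop("recording has no trials")
  reasons <- vapply(trials, function(tr) {
    keys <- tr[tr$code %in% c("KEY_LEFT", "KEY_RIGHT"), , drop = FALSE]
    if (nrow(keys) != 2) return("malformed")
    expected <- vapply(task_fingers(tr$task[1]), finger_code, "")
    if (!identical(keys$code, unname(expected))) return("wrong_key")
    if ((keys$sample[2] - keys$sample[1]) / rec$rate > max_gap)
      return("late_key")
    ""
  }, character(1))
  dropped <- which(reasons != "")
  list(kept = which(reasons == ""),
       dropped = data.frame(
         trial = dropped,
         task = vapply(trials[dropped], function(tr) tr$task[1], ""),
         reason = reasons[dropped], stringsAsFactors = FALSE))
}

#' Keep only the listed trials in a recording's event stream
#'
#' Removes the events of all other trials so that later epoching sees only
#' retained trials.
#'
#' @param rec an [eeg_recording].
#' @param kept trial indices to keep (as from [reject_bad_trials()]).
#' @return the recording with a filtered event table.
#' @export
keep_trials <- function(rec, kept) {
  trials <- split_trials(rec$events)
  ev <- do.call(rbind, trials[kept])
  rec$events <- validate_events(ev[order(ev$sample), ], ncol(rec$data))
  rec
}
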