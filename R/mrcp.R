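#' MRCP preprocessing pipeline
#'
#' Movement-related cortical potentials are slow (< 3 Hz) waveforms, so the
#' recording is downsampled to 16 Hz, low-pass filtered at 3 Hz (4th-order
#' zero-phase Butterworth), re-referenced to the common average and epoched
#' `[-2, 3)` s around the first keystroke of each trial.
#'
#' @param rec an [eeg_recording] (trial-rejected upstream if desired).
#' @param tmin,tmax epoch window in seconds.
#' @return an [eeg_epochs] at 16 Hz.
#' @export
mrcp_pipeline <- function(rec, tmin = -2, tmax = 3) {
  rec <- resample_to(rec, 16)
  rec <- butterworth_filter(rec, high = 3, order = 4)
  rec <- common_average_reference(rec)
  extract_epochs(rec, tmin, tmax, anchor = "first_key")
}

#' Grand-average waveforms per task
#'
#' Averages epochs within each task. When a subject partition is given,
#' trials are first averaged within subject, then subject means are averaged
#' (subjects are the statistical units), and the per-subject means are
#' retained for paired statistics.
#'
#' @param epochs an [eeg_epochs].
#' @param subjects optional per-trial subject identifier vector.
#' @return `mrcp_result`: `waveforms` (task -> channels x time matrix),
#'   `subject_means` (task -> subject x channels x time array or NULL),
#'   `times`, `channels`, `rate`.
#' @export
grand_average <- function(epochs, subjects = NULL) {
  tasks <- sort(unique(epochs$labels))
  times <- epoch_times(epochs)
  waveforms <- list(); subject_means <- NULL
  if (!is.null(subjects) && length(subjects) != length(epochs$labels))
    stop("subjects must have one entry per trial")
  for (task in tasks) {
    idx <- which(epochs$labels == task)
    if (length(idx) == 0) next
    if (is.null(subjects)) {
      waveforms[[task]] <-
        apply(epochs$data[idx, , , drop = FALSE], c(2, 3), mean)
    } else {
      subs <- sort(unique(subjects[idx]))
      sm <- array(0, dim = c(length(subs), dim(epochs$data)[2],
                             dim(epochs$data)[3]),
                  dimnames = list(as.character(subs), NULL, NULL))
      for (j in seq_along(subs)) {
        rows <- idx[subjects[idx] == subs[j]]
        sm[j, , ] <- apply(epochs$data[rows, , , drop = FALSE], c(2, 3), mean)
      }
      if (is.null(subject_means)) subject_means <- list()
      subject_means[[task]] <- sm
      waveforms[[task]] <- apply(sm, c(2, 3), mean)
    }
  }
  empty <- setdiff(unique(epochs$labels), names(waveforms))
  if (length(empty)) warning("tasks without epochs excluded: ",
                             paste(empty, collapse = ", "))
  structure(list(waveforms = waveforms, subject_means = subject_means,
                 times = times, channels = epochs$channels,
                 rate = epochs$rate),
            class = "mrcp_result")
}

#' @export
print.mrcp_result <- function(x, ...) {
  cat("<mrcp_result> tasks: ", paste(names(x$waveforms), collapse = ", "),
      "; ", length(x$channels), " ch x ", length(x$times), " time points\n",
      sep = "")
  invisible(x)
}

#' Pointwise paired t-test between two conditions
#'
#' Two-sided paired t-test at every time point over matched subject means.
#' Time points where the paired differences have zero variance are flagged
#' degenerate and reported with p = 1 (no evidence either way).
#'
#' @param cond_a,cond_b subject x time matrices with matched rows.
#' @param alpha significance level for the mask (default 0.05).
#' @return `pointwise_test`: `t_values`, `p_values`, `sig_mask`,
#'   `degenerate`, `alpha`, `df`.
#' @export
pointwise_paired_ttest <- function(cond_a, cond_b, alpha = 0.05) {
  cond_a <- as.matrix(cond_a); cond_b <- as.matrix(cond_b)
  if (!all(dim(cond_a) == dim(cond_b)))
    stop("conditions must share subjects and time grid")
  n <- nrow(cond_a)
  if (n < 2) stop("paired t-test needs >= 2 subjects")
  d <- cond_a - cond_b
  mn <- colMeans(d)
  sd_ <- apply(d, 2, stats::sd)
  degenerate <- sd_ < .Machine$double.eps^0.5 * (abs(mn) + 1)
  t_values <- ifelse(degenerate, 0, mn / (sd_ / sqrt(n)))
  p_values <- ifelse(degenerate, 1,
                     2 * stats::pt(-abs(t_values), df = n - 1))
  structure(list(t_values = t_values, p_values = p_values,
                 sig_mask = p_values < alpha, degenerate = degenerate,
                 alpha = alpha, df = n - 1),
            class = "pointwise_test")
}

#' Topography values at selected time points
#'
#' For each task, reads the grand-average value of every channel at the
#' grid point nearest each requested time (the defaults probe the first and
#' second sub-action: -150 ms and 850 ms).
#'
#' @param result an `mrcp_result` from [grand_average()].
#' @param times requested times in seconds, inside the epoch window.
#' @return data.frame `task`, `requested_time`, `grid_time`, `channel`,
#'   `value`.
#' @export
topography_at <- function(result, times = c(-0.150, 0.850)) {
  grid <- result$times
  out <- list()
  for (tm in times) {
    if (tm < min(grid) || tm > max(grid))
      stop("requested time ", tm, " s outside epoch window [",
           min(grid), ", ", max(grid), "]")
    i <- which.min(abs(grid - tm))
    for (task in names(result$waveforms)) {
      out[[length(out) + 1]] <- data.frame(
        task = task, requested_time = tm, grid_time = grid[i],
        channel = result$channels,
        value = result$waveforms[[task]][, i],
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
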