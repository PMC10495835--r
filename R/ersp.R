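#' ERSP preprocessing pipeline
#'
#' Time-frequency analysis runs at 200 Hz: the recording is downsampled,
#' re-referenced to the common average, band-passed 4-30 Hz (zero-phase
#' Butterworth) and epoched around the first keystroke with enough margin
#' beyond the -1.5..2.5 s reporting range to hold half an STFT window at
#' each end.
#'
#' @param rec an [eeg_recording].
#' @param trange reporting time range in seconds.
#' @param window_len STFT window length in samples (at 200 Hz).
#' @return an [eeg_epochs] at 200 Hz.
#' @export
ersp_pipeline <- function(rec, trange = c(-1.5, 2.5), window_len = 256) {
  rec <- resample_to(rec, 200)
  rec <- common_average_reference(rec)
  rec <- butterworth_filter(rec, low = 4, high = 30, order = 4)
  half <- window_len / 2 / 200
  extract_epochs(rec, trange[1] - half, trange[2] + half,
                 anchor = "first_key")
}

# Hanning-window STFT power of one epoch channel. Returns freqs x frames
# power (PSD scaling) at the given frame-centre sample indices (1-based).
stft_power <- function(x, rate, centers, window_len) {
  w <- signal::hanning(window_len)
  half <- window_len / 2
  scale <- 1 / (rate * sum(w^2))
  nf <- window_len / 2 + 1
  out <- matrix(0, nf, length(centers))
  for (j in seq_along(centers)) {
    seg <- x[(centers[j] - half):(centers[j] + half - 1)] * w
    X <- stats::fft(seg)[seq_len(nf)]
    p <- (Mod(X)^2) * scale
    p[2:(nf - 1)] <- 2 * p[2:(nf - 1)]   # fold negative frequencies
    out[, j] <- p
  }
  out
}

#' Event-related spectral perturbation per task
#'
#' Per channel, short-time Fourier transform (Hanning window, default 256
#' samples, 25% hop) power is averaged over the trials of each task,
#' converted to decibels, linearly interpolated onto the reporting time
#' grid, and baseline-corrected by subtracting the per-frequency mean over
#' the baseline window: `ERSP = ERSP_original - ERSP_baseline`. Negative
#' values are ERD, positive ERS.
#'
#' @param epochs an [eeg_epochs] at 200 Hz from [ersp_pipeline()].
#' @param window_len Hanning window length in samples.
#' @param hop frame hop in samples (default `window_len / 4`).
#' @param baseline baseline window (s), inside `trange`.
#' @param trange reporting range (s).
#' @param grid_step reporting grid step (s).
#' @param fband analysis band (Hz) kept in the output.
#' @param db report decibels (default) or raw power ratio-free values.
#' @return named list (one `ersp_map` per task): `values` (channels x
#'   freqs x times, baseline-subtracted), `original`, `baseline`, `freqs`,
#'   `times`, `channels`.
#' @export
compute_ersp <- function(epochs, window_len = 256, hop = window_len / 4,
                         baseline = c(-1.5, -1.0), trange = c(-1.5, 2.5),
                         grid_step = 0.1, fband = c(4, 30), db = TRUE) {
  rate <- epochs$rate
  if (baseline[1] < trange[1] || baseline[2] > trange[2])
    stop("baseline window must lie inside the reporting range")
  times_all <- epoch_times(epochs)
  half <- window_len / 2
  # frame centres at the native hop, covering the reporting range
  valid <- (half + 1):(dim(epochs$data)[3] - half + 1)
  centers <- valid[seq(1, length(valid), by = hop)]
  last <- valid[length(valid)]
  if (centers[length(centers)] != last) centers <- c(centers, last)
  frame_t <- times_all[centers]
  tol <- 1 / rate
  if (min(frame_t) > trange[1] + tol || max(frame_t) < trange[2] - tol)
    stop("epochs too short for the reporting range plus window padding")
  frame_t[1] <- min(frame_t[1], trange[1])      # guard interpolation edges
  frame_t[length(frame_t)] <- max(frame_t[length(frame_t)], trange[2])
  freqs_all <- (0:(window_len / 2)) * rate / window_len
  fsel <- which(freqs_all >= fband[1] & freqs_all <= fband[2])
  grid <- seq(trange[1], trange[2], by = grid_step)
  n_ch <- dim(epochs$data)[2]
  tasks <- sort(unique(epochs$labels))

  out <- list()
  for (task in tasks) {
    idx <- which(epochs$labels == task)
    pow <- array(0, dim = c(n_ch, length(fsel), length(centers)))
    for (tr in idx)
      for (ch in seq_len(n_ch))
        pow[ch, , ] <- pow[ch, , ] +
          stft_power(epochs$data[tr, ch, ], rate, centers,
                     window_len)[fsel, , drop = FALSE]
    pow <- pow / length(idx)                 # trial-average power, then dB
    if (db) pow <- 10 * log10(pmax(pow, .Machine$double.xmin))
    vals <- array(0, dim = c(n_ch, length(fsel), length(grid)))
    for (ch in seq_len(n_ch))
      for (fi in seq_along(fsel))
        vals[ch, fi, ] <- stats::approx(frame_t, pow[ch, fi, ],
                                        xout = grid)$y
    base_idx <- which(grid >= baseline[1] & grid <= baseline[2])
    base <- apply(vals[, , base_idx, drop = FALSE], c(1, 2), mean)
    corrected <- sweep(vals, c(1, 2), base)
    out[[task]] <- structure(
      list(values = corrected, original = vals, baseline = base,
           freqs = freqs_all[fsel], times = grid,
           baseline_window = baseline, channels = epochs$channels),
      class = "ersp_map")
  }
  out
}

#' @export
print.ersp_map <- function(x, ...) {
  cat("<ersp_map> ", length(x$channels), " ch x ", length(x$freqs),
      " freqs (", min(x$freqs), "-", max(x$freqs), " Hz) x ",
      length(x$times), " times\n", sep = "")
  invisible(x)
}

#' Band-averaged ERSP topography
#'
#' Mean baseline-subtracted ERSP over a frequency band and time window per
#' channel; the default 8-13 Hz band with windows (-0.5, 0.5) and
#' (0.5, 1.5) s probes the alpha ERD of the first and second sub-action.
#'
#' @param ersp_maps named list of `ersp_map` from [compute_ersp()].
#' @param band frequency band (Hz).
#' @param windows list of time windows (s).
#' @return data.frame `task`, `window_start`, `window_end`, `channel`,
#'   `value` (dB).
#' @export
band_topography <- function(ersp_maps, band = c(8, 13),
                            windows = list(c(-0.5, 0.5), c(0.5, 1.5))) {
  if (!is.list(windows[[1]]) && !is.numeric(windows[[1]]))
    stop("windows must be a list of length-2 numeric vectors")
  out <- list()
  for (task in names(ersp_maps)) {
    m <- ersp_maps[[task]]
    fidx <- which(m$freqs >= band[1] & m$freqs <= band[2])
    if (length(fidx) == 0) stop("band outside the analysis frequencies")
    for (w in windows) {
      tidx <- which(m$times >= w[1] & m$times <= w[2])
      if (length(tidx) == 0) stop("empty time window selection")
      vals <- apply(m$values[, fidx, tidx, drop = FALSE], 1, mean)
      out[[length(out) + 1]] <- data.frame(
        task = task, window_start = w[1], window_end = w[2],
        channel = m$channels, value = vals, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
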