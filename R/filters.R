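# Zero-phase IIR filtering with odd-symmetric edge reflection (the
# MATLAB-style padding convention), applied forward and backward.
apply_zerophase <- function(b, a, x, pad = NULL) {
  n <- length(x)
  if (is.null(pad)) pad <- min(n - 1, max(3 * (max(length(a), length(b)) - 1), 300))
  if (pad > 0) {
    head_ref <- 2 * x[1] - x[(pad + 1):2]
    tail_ref <- 2 * x[n] - x[(n - 1):(n - pad)]
    xe <- c(head_ref, x, tail_ref)
  } else xe <- x
  y <- signal::filter(b, a, xe)
  y <- rev(signal::filter(b, a, rev(y)))
  y[(pad + 1):(pad + n)]
}

filter_matrix <- function(b, a, m, pad = NULL) {
  t(apply(m, 1, function(row) apply_zerophase(b, a, row, pad)))
}

# Apply fn(channels x samples matrix, rate) to a recording or every epoch.
map_signal <- function(x, fn) {
  if (inherits(x, "eeg_recording")) {
    x$data <- fn(x$data, x$rate)
    x
  } else if (inherits(x, "eeg_epochs")) {
    for (i in seq_len(dim(x$data)[1]))
      x$data[i, , ] <- fn(x$data[i, , , drop = TRUE], x$rate)
    x
  } else stop("expected an eeg_recording or eeg_epochs")
}

signal_rate <- function(x) {
  if (inherits(x, c("eeg_recording", "eeg_epochs"))) x$rate
  else stop("expected an eeg_recording or eeg_epochs")
}

#' Notch filter for line interference
#'
#' Second-order IIR notch (biquad) at `freq`, applied zero-phase. With the
#' default quality factor the 50 Hz line is suppressed far beyond 30 dB
#' while the passband stays within 1 dB.
#'
#' @param x an [eeg_recording] or [eeg_epochs].
#' @param freq notch centre frequency in Hz (default 50, must be < Nyquist).
#' @param q quality factor (centre / -3 dB width).
#' @return same type as `x`, filtered.
#' @export
notch_filter <- function(x, freq = 50, q = 30) {
  rate <- signal_rate(x)
  if (freq >= rate / 2)
    stop("notch frequency ", freq, " Hz is not below Nyquist (", rate / 2, ")")
  w0 <- 2 * pi * freq / rate
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1) / (1 + alpha)
  a <- c(1, -2 * cos(w0) / (1 + alpha), (1 - alpha) / (1 + alpha))
  map_signal(x, function(m, r) filter_matrix(b, a, m))
}

#' Zero-phase Butterworth filter
#'
#' Designs a Butterworth filter of the stated order (per edge, MATLAB
#' convention) and applies it forward-backward, doubling the effective
#' magnitude order and cancelling the phase. Give `low` only for a
#' high-pass, `high` only for a low-pass, both for a band-pass.
#'
#' @param x an [eeg_recording] or [eeg_epochs].
#' @param low lower passband edge in Hz, or `NULL`.
#' @param high upper passband edge in Hz, or `NULL`.
#' @param order filter order of the single-pass design (default 4).
#' @return same type as `x`, filtered.
#' @export
butterworth_filter <- function(x, low = NULL, high = NULL, order = 4) {
  rate <- signal_rate(x)
  ny <- rate / 2
  if (is.null(low) && is.null(high)) stop("set at least one of low/high")
  for (f in c(low, high))
    if (f <= 0 || f >= ny) stop("cutoff ", f, " Hz outside (0, Nyquist)")
  flt <- if (!is.null(low) && !is.null(high)) {
    if (low >= high) stop("low cutoff must be below high cutoff")
    signal::butter(order, c(low, high) / ny, type = "pass")
  } else if (!is.null(high)) {
    signal::butter(order, high / ny, type = "low")
  } else {
    signal::butter(order, low / ny, type = "high")
  }
  lowest <- min(c(low, high))
  pad <- max(600, round(3 * rate / lowest))
  map_signal(x, function(m, r)
    filter_matrix(flt$b, flt$a, m, pad = min(ncol(m) - 1, pad)))
}

rhafz <- function(x) sign(x) * floor(abs(x) + 0.5) # round half away from zero

#' Resample a recording or epochs
#'
#' Anti-alias low-pass filtering (zero-phase Butterworth at 45% of the
#' target rate) followed by interpolation onto the target grid. Event
#' sample indices are rescaled by `target/rate` with round-half-away-from-
#' zero. Upsampling is refused unless explicitly allowed.
#'
#' @param x an [eeg_recording] or [eeg_epochs].
#' @param target_rate new sampling rate in Hz.
#' @param allow_upsample permit `target_rate > rate`.
#' @return same type as `x` at `target_rate`.
#' @export
resample_to <- function(x, target_rate, allow_upsample = FALSE) {
  rate <- signal_rate(x)
  if (target_rate <= 0) stop("target_rate must be positive")
  if (target_rate == rate) return(x)
  if (target_rate > rate && !allow_upsample)
    stop("upsampling from ", rate, " to ", target_rate,
         " Hz is disabled (allow_upsample = FALSE)")
  down <- function(m, r) {
    n <- ncol(m)
    if (target_rate < r) {
      flt <- signal::butter(4, 0.9 * target_rate / r, type = "low")
      pad <- min(n - 1, max(600, round(3 * r / (0.45 * target_rate))))
      m <- filter_matrix(flt$b, flt$a, m, pad = pad)
    }
    n_out <- round(n * target_rate / r)
    t_old <- (seq_len(n) - 1) / r
    t_new <- (seq_len(n_out) - 1) / target_rate
    t_new <- pmin(t_new, t_old[n])
    t(apply(m, 1, function(row)
      stats::approx(t_old, row, xout = t_new)$y))
  }
  if (inherits(x, "eeg_recording")) {
    x$data <- down(x$data, rate)
    x$events$sample <- as.integer(rhafz(x$events$sample * target_rate / rate))
    x$events <- validate_events(x$events, ncol(x$data))
    x$rate <- target_rate
    x
  } else {
    n_out <- round(dim(x$data)[3] * target_rate / rate)
    arr <- array(0, dim = c(dim(x$data)[1], dim(x$data)[2], n_out))
    for (i in seq_len(dim(x$data)[1]))
      arr[i, , ] <- down(x$data[i, , , drop = TRUE], rate)
    eeg_epochs(arr, x$labels, x$tmin, x$tmin + n_out / target_rate,
               target_rate, x$channels)
  }
}

#' Common average reference
#'
#' Subtracts the instantaneous mean over channels from every channel, so
#' the channel mean is exactly zero at every sample.
#'
#' @param x an [eeg_recording] or [eeg_epochs] with >= 2 channels.
#' @return same type as `x`, re-referenced (recordings marked `CAR`).
#' @export
common_average_reference <- function(x) {
  n_ch <- if (inherits(x, "eeg_recording")) nrow(x$data) else dim(x$data)[2]
  if (n_ch < 2) stop("CAR needs at least 2 channels")
  out <- map_signal(x, function(m, r) sweep(m, 2, colMeans(m)))
  if (inherits(out, "eeg_recording")) out$reference <- "CAR"
  out
}
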