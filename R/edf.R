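# Minimal European Data Format (EDF) writer/reader: fixed 256-byte header,
# 256 bytes per signal, 16-bit little-endian samples. Events do not travel
# in EDF here (EDF+ annotations are out of scope); they use the sidecar.

pad_field <- function(x, width) {
  s <- substr(as.character(x), 1, width)
  formatC(s, width = -width, flag = " ")
}

num_field <- function(x, width) {
  s <- formatC(x, format = "g", digits = 7)
  if (grepl("[eE]", s) || nchar(s) > width) {
    # fall back to fixed notation that fits the field
    int_len <- nchar(sprintf("%.0f", x))
    s <- formatC(x, format = "f",
                 digits = max(0, width - int_len - 1))
    s <- substr(s, 1, width)
  }
  pad_field(s, width)
}

write_edf <- function(rec, path) {
  n_ch <- nrow(rec$data)
  n <- ncol(rec$data)
  if (n == 0) stop("refusing to write an empty recording")
  # 1 s records when the length divides evenly, else one long record
  if (rec$rate == round(rec$rate) && n %% rec$rate == 0) {
    spr <- as.integer(rec$rate); dur <- 1; n_rec <- n %/% spr
  } else {
    spr <- n; dur <- n / rec$rate; n_rec <- 1L
  }
  pmin <- apply(rec$data, 1, min)
  pmax <- apply(rec$data, 1, max)
  flat <- pmax - pmin < 1e-9
  pmin[flat] <- pmin[flat] - 1
  pmax[flat] <- pmax[flat] + 1
  # quantise the physical range to its 8-char header representation so the
  # reader reconstructs with the exact same scale
  pmin <- as.numeric(vapply(pmin, num_field, "", width = 8))
  pmax <- as.numeric(vapply(pmax, num_field, "", width = 8))
  pmax <- pmax + (pmax <= pmin)          # guard degenerate rounding
  dmin <- -32768; dmax <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad_field("0", 8), pad_field("X", 80), pad_field("seqfinger", 80),
    pad_field("01.01.26", 8), pad_field("00.00.00", 8),
    pad_field(256 * (1 + n_ch), 8), pad_field("", 44),
    pad_field(n_rec, 8), num_field(dur, 8), pad_field(n_ch, 4))
  writeChar(hdr, con, eos = NULL)
  fields <- list(
    vapply(rec$montage$names, pad_field, "", width = 16),
    rep(pad_field("AgAgCl", 80), n_ch),
    rep(pad_field("uV", 8), n_ch),
    vapply(pmin, num_field, "", width = 8),
    vapply(pmax, num_field, "", width = 8),
    rep(pad_field(dmin, 8), n_ch),
    rep(pad_field(dmax, 8), n_ch),
    rep(pad_field("", 80), n_ch),
    rep(pad_field(spr, 8), n_ch),
    rep(pad_field("", 32), n_ch))
  for (f in fields) writeChar(paste0(f, collapse = ""), con, eos = NULL)

  scale <- (dmax - dmin) / (pmax - pmin)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * spr + 1):(r * spr)
    for (ch in seq_len(n_ch)) {
      dig <- round((rec$data[ch, idx] - pmin[ch]) * scale[ch] + dmin)
      writeBin(as.integer(pmin(pmax(dig, dmin), dmax)), con, size = 2,
               endian = "little")
    }
  }
  invisible(path)
}

read_edf <- function(path, events = empty_events()) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8); rd(44)
  n_rec <- as.integer(rd(8))
  dur <- as.numeric(rd(8))
  n_ch <- as.integer(rd(4))
  per <- function(w) vapply(seq_len(n_ch), function(i) rd(w), "")
  labels <- per(16); per(80); per(8)
  pmin <- as.numeric(per(8)); pmax <- as.numeric(per(8))
  dmin <- as.numeric(per(8)); dmax <- as.numeric(per(8))
  per(80)
  spr <- as.integer(per(8)); per(32)
  if (length(unique(spr)) != 1)
    stop("mixed per-signal rates are not supported")
  spr <- spr[1]
  rate <- spr / dur
  data <- matrix(0, n_ch, n_rec * spr)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * spr + 1):(r * spr)
    for (ch in seq_len(n_ch)) {
      dig <- readBin(con, integer(), n = spr, size = 2, endian = "little",
                     signed = TRUE)
      data[ch, idx] <- (dig - dmin[ch]) / (dmax[ch] - dmin[ch]) *
        (pmax[ch] - pmin[ch]) + pmin[ch]
    }
  }
  pos <- tryCatch(t(vapply(labels, position_1020, numeric(2))),
                  error = function(e) {
                    ang <- 2 * pi * (seq_len(n_ch) - 1) / n_ch
                    cbind(cos(ang), sin(ang))
                  })
  eeg_recording(data, rate, montage(labels, pos), events, reference = "nose")
}
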