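#' @name recording_io
#' @title Read and write continuous recordings
#'
#' @description
#' Two on-disk forms are supported. The `delimited` form is fully
#' text-based: `<stem>.tsv` holds the signal (one column per channel, one
#' row per sample, microvolts), `<stem>.meta.yaml` the sampling rate,
#' channel names, positions, units and reference, and `<stem>.events.tsv`
#' the event table (`sample  code  task`, sample 0-based). The `edf` form
#' writes `<stem>.edf` (16-bit European Data Format) plus the same events
#' sidecar. EDF quantises to the 16-bit digital range, so round-trips are
#' exact only to writer precision.
NULL

events_path <- function(stem) paste0(stem, ".events.tsv")
meta_path <- function(stem) paste0(stem, ".meta.yaml")

strip_ext <- function(path) sub("\\.(edf|tsv)$", "", path, ignore.case = TRUE)

write_events_table <- function(events, path) {
  utils::write.table(events, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
}

read_events_table <- function(path) {
  if (!file.exists(path)) return(empty_events())
  ev <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c("integer", "character", "character"),
                          na.strings = "")
  ev
}

#' Save a continuous recording
#'
#' @param rec an [eeg_recording].
#' @param path destination path; extension chooses the stem (`.edf`/`.tsv`
#'   stripped). Companion files are written next to it.
#' @param format `"delimited"` or `"edf"`.
#' @return the main written path, invisibly usable by [load_recording()].
#' @export
save_recording <- function(rec, path, format = c("delimited", "edf")) {
  format <- match.arg(format)
  if (!inherits(rec, "eeg_recording")) stop("rec must be an eeg_recording")
  if (ncol(rec$data) == 0) stop("refusing to save an empty recording (0 samples)")
  stem <- strip_ext(path)
  dir.create(dirname(stem), recursive = TRUE, showWarnings = FALSE)
  if (format == "delimited") {
    main <- paste0(stem, ".tsv")
    df <- as.data.frame(t(rec$data))
    names(df) <- rec$montage$names
    utils::write.table(df, main, sep = "\t", quote = FALSE, row.names = FALSE)
    meta <- list(rate = rec$rate, units = "microvolts",
                 reference = rec$reference,
                 channels = as.list(rec$montage$names),
                 positions = lapply(seq_len(length(rec$montage)), function(i)
                   as.numeric(rec$montage$positions[i, ])))
    yaml::write_yaml(meta, meta_path(stem))
  } else {
    main <- paste0(stem, ".edf")
    write_edf(rec, main)
  }
  write_events_table(rec$events, events_path(stem))
  invisible(main)
}

#' Load a continuous recording
#'
#' @param path path written by [save_recording()] (the `.tsv`/`.edf` file or
#'   its stem).
#' @param format `"delimited"` or `"edf"`; guessed from the extension when
#'   missing.
#' @return an [eeg_recording] in microvolts.
#' @export
load_recording <- function(path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf"
              else "delimited"
  }
  format <- match.arg(format, c("delimited", "edf"))
  stem <- strip_ext(path)
  events <- read_events_table(events_path(stem))
  if (format == "delimited") {
    main <- paste0(stem, ".tsv")
    if (!file.exists(main)) stop("no such file: ", main)
    mp <- meta_path(stem)
    if (!file.exists(mp))
      stop("delimited recordings need a sidecar metadata file: ", mp)
    meta <- yaml::read_yaml(mp)
    df <- utils::read.table(main, sep = "\t", header = TRUE,
                            check.names = FALSE)
    chans <- unlist(meta$channels)
    if (!setequal(names(df), chans) || ncol(df) != length(chans))
      stop("channel mismatch between data columns and sidecar metadata")
    pos <- do.call(rbind, meta$positions)
    mont <- montage(chans, pos)
    data <- t(as.matrix(df[, chans, drop = FALSE]))
    eeg_recording(data, meta$rate, mont, events,
                  reference = meta$reference %||% "nose")
  } else {
    read_edf(paste0(stem, ".edf"), events = events)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read pipeline configuration
#'
#' Thin wrapper over a YAML file naming pipeline parameters; returns a
#' nested list with absent fields left to function defaults.
#' @param path YAML file.
#' @return named list.
#' @export
read_config <- function(path) yaml::read_yaml(path)
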