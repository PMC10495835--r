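#' Channel montage
#'
#' A montage is an ordered set of scalp electrode labels with 2-D projected
#' positions used for spatial weighting in the simulator and for topography
#' export. Positions follow the usual top-view convention: x increases to the
#' subject's right, y towards the nasion, head radius ~1.
#'
#' @param names character vector of unique channel labels.
#' @param positions numeric matrix (channels x 2) of finite 2-D coordinates,
#'   rows in the order of `names`.
#' @return An object of class `montage`: list with `names` and `positions`.
#' @export
montage <- function(names, positions) {
  names <- as.character(names)
  positions <- as.matrix(positions)
  if (anyDuplicated(names)) stop("montage channel names must be unique")
  if (nrow(positions) != length(names) || ncol(positions) != 2)
    stop("positions must be a (channels x 2) matrix matching 'names'")
  if (!all(is.finite(positions))) stop("montage positions must be finite")
  rownames(positions) <- names
  structure(list(names = names, positions = positions), class = "montage")
}

#' @export
print.montage <- function(x, ...) {
  cat("<montage> ", length(x$names), " channels: ",
      paste(utils::head(x$names, 6), collapse = ", "),
      if (length(x$names) > 6) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' @export
length.montage <- function(x) length(x$names)

# Approximate 10-20/10-10 grid: anterior-posterior row -> y, lateral
# column -> x (odd numbers left/negative, even right/positive, z midline).
row_y <- c(FP = 0.90, AF = 0.70, F = 0.50, FT = 0.30, FC = 0.25,
           T = 0.00, C = 0.00, TP = -0.30, CP = -0.25, P = -0.50,
           PO = -0.70, O = -0.90)
col_x <- c("0" = 0, "1" = 0.15, "2" = 0.15, "3" = 0.40, "4" = 0.40,
           "5" = 0.65, "6" = 0.65, "7" = 0.90, "8" = 0.90)

position_1020 <- function(label) {
  m <- regmatches(label, regexec("^([A-Z]+)(Z|[0-9])$", label))[[1]]
  if (length(m) == 0) stop("cannot place channel label: ", label)
  row <- m[2]; col <- m[3]
  if (!row %in% names(row_y)) stop("unknown 10-20 row: ", row)
  y <- row_y[[row]]
  if (col == "Z") return(c(0, y))
  n <- as.integer(col)
  x <- col_x[[col]]
  # AF/PO rings are narrower than the central rings
  if (row %in% c("AF", "PO")) x <- x * 0.8
  if (n %% 2 == 1) x <- -x
  c(x, y)
}

#' Standard 60-channel 10-20 montage
#'
#' The default layout: a 60-electrode subset of the extended 10-20 system
#' covering frontal through occipital rows, including the sensorimotor
#' channels C3, Cz and C4 used throughout the analyses.
#'
#' @return A [montage] with 60 channels.
#' @export
standard_montage_60 <- function() {
  labs <- c("FP1", "FPZ", "FP2", "AF3", "AF4",
            "F7", "F5", "F3", "F1", "FZ", "F2", "F4", "F6", "F8",
            "FT7", "FC5", "FC3", "FC1", "FCZ", "FC2", "FC4", "FC6", "FT8",
            "T7", "C5", "C3", "C1", "CZ", "C2", "C4", "C6", "T8",
            "TP7", "CP5", "CP3", "CP1", "CPZ", "CP2", "CP4", "CP6", "TP8",
            "P7", "P5", "P3", "P1", "PZ", "P2", "P4", "P6", "P8",
            "PO7", "PO5", "PO3", "POZ", "PO4", "PO6", "PO8",
            "O1", "OZ", "O2")
  pos <- t(vapply(labs, position_1020, numeric(2)))
  montage(labs, pos)
}

#' Pairwise channel distances of a montage
#' @param mont a [montage].
#' @return symmetric (channels x channels) Euclidean distance matrix.
#' @export
montage_distances <- function(mont) {
  as.matrix(stats::dist(mont$positions))
}

# Index of a named channel, with a clear error.
channel_index <- function(mont, label) {
  i <- match(toupper(label), toupper(mont$names))
  if (is.na(i)) stop("channel not in montage: ", label)
  i
}

# Require the sensorimotor channels used by MRCP/ERSP analyses.
require_sensorimotor <- function(mont) {
  missing <- setdiff(c("C3", "CZ", "C4"), toupper(mont$names))
  if (length(missing))
    stop("montage lacks sensorimotor channels: ", paste(missing, collapse = ", "))
  invisible(TRUE)
}
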