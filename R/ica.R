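# FastICA (symmetric orthogonalisation, logcosh contrast) on PCA-whitened
# data. Input m: channels x samples, already centred.
fast_ica_core <- function(m, n_components, max_iter = 200, tol = 1e-6,
                          seed = 1) {
  n_ch <- nrow(m); n <- ncol(m)
  if (n_components > n_ch) stop("n_components exceeds channel count")
  sv <- svd(m, nu = n_components, nv = 0)
  keep <- seq_len(n_components)
  K <- diag(1 / sv$d[keep] * sqrt(n), n_components) %*% t(sv$u[, keep])
  Z <- K %*% m                              # whitened: cov ~ I
  set.seed(seed)
  W <- matrix(stats::rnorm(n_components^2), n_components)
  orth <- function(W) {
    s <- svd(W)
    s$u %*% t(s$v)
  }
  W <- orth(W)
  for (it in seq_len(max_iter)) {
    WZ <- W %*% Z
    G <- tanh(WZ)
    gprime <- rowMeans(1 - G^2)
    W1 <- G %*% t(Z) / n - diag(gprime, n_components) %*% W
    W1 <- orth(W1)
    delta <- max(abs(abs(diag(W1 %*% t(W))) - 1))
    W <- W1
    if (delta < tol) break
  }
  unmixing <- W %*% K                       # components x channels
  sources <- unmixing %*% m
  # right pseudo-inverse: channels x components, unmixing %*% mixing = I
  mixing <- t(unmixing) %*% solve(unmixing %*% t(unmixing))
  list(mixing = mixing, unmixing = unmixing, sources = sources)
}

#' ICA-based artifact removal
#'
#' Decomposes the recording into independent components (FastICA on a
#' PCA-reduced subspace), flags artifact components by a reproducible
#' criterion, zeroes them and reconstructs the signal. The default
#' criterion flags components whose source time course correlates with an
#' EOG reference beyond `threshold`; the reference is either a frontal
#' channel label or an externally supplied blink regressor.
#'
#' @param rec an [eeg_recording].
#' @param n_components number of components to estimate (<= channel count).
#' @param criterion `"eog_correlation"` or `"variance_threshold"` (flags
#'   components whose variance share exceeds `threshold`).
#' @param eog_reference channel label or numeric time course (required for
#'   the correlation criterion).
#' @param threshold absolute-correlation (or variance-share) cutoff.
#' @param seed seed for the FastICA initialisation.
#' @return list: `rec` (cleaned recording), `decomposition` (class
#'   `artifact_decomposition`: `mixing`, `unmixing`, `sources`, `removed`).
#' @export
ica_artifact_removal <- function(rec, n_components = 20,
                                 criterion = c("eog_correlation",
                                               "variance_threshold"),
                                 eog_reference = NULL, threshold = 0.8,
                                 seed = 1) {
  criterion <- match.arg(criterion)
  if (n_components > nrow(rec$data))
    stop("n_components exceeds channel count")
  if (ncol(rec$data) < 10 * n_components)
    stop("recording too short for ", n_components, " components")
  center <- rowMeans(rec$data)
  m <- rec$data - center
  dec <- fast_ica_core(m, n_components, seed = seed)

  removed <- integer(0)
  if (criterion == "eog_correlation") {
    if (is.null(eog_reference))
      stop("eog_correlation criterion needs an eog_reference")
    ref <- if (is.character(eog_reference))
      rec$data[channel_index(rec$montage, eog_reference), ]
    else as.numeric(eog_reference)
    if (length(ref) != ncol(rec$data))
      stop("eog_reference length must match the recording")
    if (stats::sd(ref) > 0) {
      r <- abs(apply(dec$sources, 1, stats::cor, y = ref))
      removed <- which(r > threshold)
    }
  } else {
    share <- rowSums(dec$sources^2)
    share <- share / sum(share)
    removed <- which(share > threshold)
  }

  clean <- m
  if (length(removed))
    clean <- m - dec$mixing[, removed, drop = FALSE] %*%
      dec$sources[removed, , drop = FALSE]
  rec$data <- clean + center
  rownames(rec$data) <- rec$montage$names
  dec$removed <- removed
  class(dec) <- "artifact_decomposition"
  list(rec = rec, decomposition = dec)
}

#' @export
print.artifact_decomposition <- function(x, ...) {
  cat("<artifact_decomposition> ", nrow(x$sources), " components, removed: ",
      if (length(x$removed)) paste(x$removed, collapse = ", ") else "none",
      "\n", sep = "")
  invisible(x)
}
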