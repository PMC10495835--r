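#' Epochs and filter-bank variants for feature extraction
#'
#' Downsamples to 200 Hz, band-pass filters the continuous signal once per
#' branch (1-8 Hz for the low-frequency MRCP branch; theta 4-8, alpha 8-13
#' and beta 13-30 Hz for the filter bank), then epochs every branch
#' `[-0.5, 1.5)` s around the first keystroke (400 samples), so both
#' keystrokes of a trial fall inside one epoch. Filtering precedes epoching
#' to keep filter transients away from the short windows.
#'
#' @param rec an [eeg_recording] (bad trials removed upstream).
#' @param tmin,tmax feature epoch window (s).
#' @param bands named list of filter-bank bands (Hz).
#' @return `feature_epochs`: `mrcp` ([eeg_epochs]), `bands` (named list of
#'   [eeg_epochs]), `labels`, `rate`, `band_defs`.
#' @export
prepare_feature_epochs <- function(rec, tmin = -0.5, tmax = 1.5,
                                   bands = list(theta = c(4, 8),
                                                alpha = c(8, 13),
                                                beta = c(13, 30))) {
  rec <- resample_to(rec, 200)
  mrcp_rec <- butterworth_filter(rec, low = 1, high = 8, order = 4)
  mrcp_ep <- extract_epochs(mrcp_rec, tmin, tmax, anchor = "first_key")
  band_ep <- lapply(bands, function(b) {
    br <- butterworth_filter(rec, low = b[1], high = b[2], order = 4)
    extract_epochs(br, tmin, tmax, anchor = "first_key")
  })
  structure(list(mrcp = mrcp_ep, bands = band_ep, labels = mrcp_ep$labels,
                 rate = 200, band_defs = bands),
            class = "feature_epochs")
}

#' @export
print.feature_epochs <- function(x, ...) {
  cat("<feature_epochs> ", length(x$labels), " trials, MRCP branch + ",
      length(x$bands), " filter-bank bands (",
      paste(names(x$bands), collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Subset a feature-epoch set by trial
#' @param fep a `feature_epochs`.
#' @param idx trial indices to keep.
#' @return `feature_epochs` restricted to `idx`.
#' @export
fep_subset <- function(fep, idx) {
  cut_ep <- function(ep) {
    eeg_epochs(ep$data[idx, , , drop = FALSE], ep$labels[idx],
               ep$tmin, ep$tmax, ep$rate, ep$channels)
  }
  structure(list(mrcp = cut_ep(fep$mrcp),
                 bands = lapply(fep$bands, cut_ep),
                 labels = fep$labels[idx], rate = fep$rate,
                 band_defs = fep$band_defs),
            class = "feature_epochs")
}

#' Replace the trial labels of a feature-epoch set
#'
#' Applies the same label vector to every branch; used for permutation
#' null checks of the decoding pipeline.
#'
#' @param fep a `feature_epochs`.
#' @param labels new per-trial labels.
#' @return the relabelled `feature_epochs`.
#' @export
fep_relabel <- function(fep, labels) {
  if (length(labels) != length(fep$labels))
    stop("labels must have one entry per trial")
  fep$labels <- as.character(labels)
  fep$mrcp$labels <- fep$labels
  for (b in names(fep$bands)) fep$bands[[b]]$labels <- fep$labels
  fep
}

# row-centre each channel of a (ch x T) epoch
center_rows <- function(m) m - rowMeans(m)

epoch_mat <- function(ep, i) ep$data[i, , , drop = TRUE]

#' Fit DCPM discriminative spatial patterns
#'
#' Discriminative canonical pattern matching on the low-frequency branch.
#' Per class (one-vs-rest), DSP filters maximize the between-class spatial
#' scatter over the within-class scatter (generalized eigenproblem with
#' shrinkage), keeping the top `n_dsp` dimensions; each class stores its
#' projected mean waveform template. Canonical-correlation alignment
#' against the template is computed at transform time.
#'
#' @param epochs [eeg_epochs] of the 1-8 Hz branch.
#' @param n_dsp spatial dimensions kept per class (default 2).
#' @param shrinkage scalar shrinkage intensity for the scatter estimates.
#' @return `dcpm_model`: per-class `filters` (ch x n_dsp), `templates`
#'   (n_dsp x T), `classes`, `eigenvalues`.
#' @export
fit_dcpm <- function(epochs, n_dsp = 2, shrinkage = 0.05) {
  classes <- sort(unique(epochs$labels))
  if (length(classes) < 2) stop("DCPM needs >= 2 classes")
  n_trial <- dim(epochs$data)[1]
  n_ch <- dim(epochs$data)[2]
  cls_mean <- lapply(classes, function(k)
    apply(epochs$data[epochs$labels == k, , , drop = FALSE], c(2, 3), mean))
  names(cls_mean) <- classes
  # within-class scatter: spatial covariance of trial deviations
  Sw <- matrix(0, n_ch, n_ch)
  for (i in seq_len(n_trial)) {
    d <- epoch_mat(epochs, i) - cls_mean[[epochs$labels[i]]]
    Sw <- Sw + tcrossprod(d)
  }
  Sw <- Sw / n_trial
  filters <- list(); templates <- list(); eigenvalues <- list()
  for (k in classes) {
    idx_k <- epochs$labels == k
    if (sum(idx_k) < 2) stop("DCPM needs >= 2 trials per class")
    rest_mean <- apply(epochs$data[!idx_k, , , drop = FALSE], c(2, 3), mean)
    d <- cls_mean[[k]] - rest_mean
    Sb <- tcrossprod(d)
    if (shrinkage == 0 && rcond(Sw) < 1e-12)
      stop("within-class scatter is singular; set shrinkage > 0")
    e <- geigen_sym(Sb, shrink_cov(Sw, shrinkage))
    W <- e$vectors[, seq_len(n_dsp), drop = FALSE]
    filters[[k]] <- W
    templates[[k]] <- t(W) %*% cls_mean[[k]]
    eigenvalues[[k]] <- e$values[seq_len(n_dsp)]
  }
  structure(list(filters = filters, templates = templates,
                 classes = classes, n_dsp = n_dsp,
                 eigenvalues = eigenvalues, shrinkage = shrinkage),
            class = "dcpm_model")
}

# canonical correlations between two (T x d) projections, padded to d
canonical_cors <- function(P, Q, d) {
  cc <- tryCatch(stats::cancor(P, Q)$cor, error = function(e) numeric(0))
  out <- rep(0, d)
  out[seq_along(cc)] <- pmin(cc, 1)
  out
}

#' DCPM features of one epoch
#'
#' For each class and each DSP dimension, two similarity values between the
#' projected epoch and the class template: the plain Pearson correlation of
#' that dimension, and the corresponding canonical correlation after CCA
#' alignment of the projected epoch with the template. With 4 classes and
#' 2 dimensions this yields the 16 ordered DCPM features.
#'
#' @param model a `dcpm_model`.
#' @param epoch channels x samples matrix on the model's grid.
#' @return numeric vector, `4 * n_dsp * 2` features (named).
#' @export
dcpm_transform <- function(model, epoch) {
  out <- numeric(0)
  for (k in model$classes) {
    P <- t(model$filters[[k]]) %*% epoch      # n_dsp x T
    Tk <- model$templates[[k]]
    if (ncol(P) != ncol(Tk)) stop("epoch grid does not match the model")
    plain <- vapply(seq_len(model$n_dsp), function(d) {
      if (stats::sd(P[d, ]) == 0 || stats::sd(Tk[d, ]) == 0) 0
      else stats::cor(P[d, ], Tk[d, ])
    }, numeric(1))
    aligned <- canonical_cors(t(P), t(Tk), model$n_dsp)
    v <- c(plain, aligned)
    names(v) <- paste0("dcpm_", k, "_",
                       c(paste0("cor", seq_len(model$n_dsp)),
                         paste0("cca", seq_len(model$n_dsp))))
    out <- c(out, v)
  }
  out
}

#' Fit task-related component analysis filters
#'
#' Per class, TRCA finds spatial filters maximizing the inter-trial
#' covariance of the time-locked response relative to total covariance
#' (generalized eigenproblem), keeping the top `n_comp` components; the
#' projected trial-average is stored as the class template.
#'
#' @param epochs [eeg_epochs] of the 1-8 Hz branch.
#' @param n_comp components kept per class (default 3).
#' @param shrinkage scalar shrinkage for the total covariance.
#' @return `trca_model`: per-class `filters` (ch x n_comp), `templates`
#'   (n_comp x T), `classes`, `objectives`.
#' @export
fit_trca <- function(epochs, n_comp = 3, shrinkage = 0.05) {
  classes <- sort(unique(epochs$labels))
  filters <- list(); templates <- list(); objectives <- list()
  n_ch <- dim(epochs$data)[2]
  for (k in classes) {
    idx <- which(epochs$labels == k)
    if (length(idx) < 2) stop("TRCA needs >= 2 trials per class")
    Xs <- lapply(idx, function(i) center_rows(epoch_mat(epochs, i)))
    Q <- matrix(0, n_ch, n_ch)
    total <- Reduce(`+`, Xs)
    for (X in Xs) Q <- Q + tcrossprod(X)
    S <- tcrossprod(total) - Q               # cross-trial covariance sum
    if (shrinkage == 0 && rcond(Q) < 1e-12)
      stop("total covariance is rank deficient; set shrinkage > 0")
    e <- geigen_sym(S, shrink_cov(Q, shrinkage))
    W <- e$vectors[, seq_len(n_comp), drop = FALSE]
    filters[[k]] <- W
    templates[[k]] <- t(W) %*% (total / length(idx))
    objectives[[k]] <- e$values[seq_len(n_comp)]
  }
  structure(list(filters = filters, templates = templates,
                 classes = classes, n_comp = n_comp,
                 objectives = objectives, shrinkage = shrinkage),
            class = "trca_model")
}

#' TRCA features of one epoch
#'
#' Per class, the epoch and the class template are projected through that
#' class's filters; the rows are concatenated and their Pearson correlation
#' is the class's feature — one value per class.
#'
#' @param model a `trca_model`.
#' @param epoch channels x samples matrix.
#' @return numeric vector, one feature per class (named).
#' @export
trca_transform <- function(model, epoch) {
  epoch <- center_rows(epoch)
  out <- vapply(model$classes, function(k) {
    P <- t(model$filters[[k]]) %*% epoch
    if (ncol(P) != ncol(model$templates[[k]]))
      stop("epoch grid does not match the model")
    a <- as.vector(P); b <- as.vector(model$templates[[k]])
    if (stats::sd(a) == 0 || stats::sd(b) == 0) 0 else stats::cor(a, b)
  }, numeric(1))
  names(out) <- paste0("trca_", model$classes)
  out
}

#' One-vs-rest CSP eigenproblem on two covariance matrices
#'
#' Solves `C1 v = lambda (C1 + C2) v`; eigenvalues lie in (0, 1) and the
#' leading eigenvectors maximize the variance share of condition 1.
#'
#' @param C1,C2 symmetric covariance matrices.
#' @param n_filters leading eigenvectors to keep.
#' @param shrinkage scalar shrinkage applied to the composite matrix.
#' @return list `filters` (ch x n_filters), `values` (all eigenvalues).
#' @export
csp_pair <- function(C1, C2, n_filters = 3, shrinkage = 0) {
  comp <- C1 + C2
  if (shrinkage == 0 && rcond(comp) < 1e-12)
    stop("composite covariance is singular; set shrinkage > 0")
  e <- geigen_sym(C1, shrink_cov(comp, shrinkage))
  list(filters = e$vectors[, seq_len(n_filters), drop = FALSE],
       values = e$values)
}

#' Fit filter-bank common spatial patterns
#'
#' Per frequency band and per class, one-vs-rest CSP on trial-averaged,
#' trace-normalized spatial covariances; the top `n_filters` eigenvectors
#' (largest class-variance share) are kept. With 4 classes, 3 bands and 3
#' filters the transform yields the 36 FBCSP features.
#'
#' @param band_epochs named list of [eeg_epochs], one per band.
#' @param n_filters filters kept per band and class (default 3).
#' @param shrinkage scalar shrinkage for the composite covariance.
#' @return `fbcsp_model`: `filters[[band]][[class]]` (ch x n_filters),
#'   `classes`, `bands`.
#' @export
fit_fbcsp <- function(band_epochs, n_filters = 3, shrinkage = 0.05) {
  first <- band_epochs[[1]]
  classes <- sort(unique(first$labels))
  filters <- list()
  for (band in names(band_epochs)) {
    ep <- band_epochs[[band]]
    covs <- lapply(seq_len(dim(ep$data)[1]), function(i) {
      X <- center_rows(epoch_mat(ep, i))
      C <- tcrossprod(X)
      C / sum(diag(C))
    })
    filters[[band]] <- list()
    for (k in classes) {
      in_k <- ep$labels == k
      if (sum(in_k) < 2 || sum(!in_k) < 2)
        stop("FBCSP needs >= 2 trials per class and rest")
      C1 <- Reduce(`+`, covs[in_k]) / sum(in_k)
      C2 <- Reduce(`+`, covs[!in_k]) / sum(!in_k)
      filters[[band]][[k]] <- csp_pair(C1, C2, n_filters, shrinkage)$filters
    }
  }
  structure(list(filters = filters, classes = classes,
                 bands = names(band_epochs), n_filters = n_filters,
                 shrinkage = shrinkage),
            class = "fbcsp_model")
}

#' FBCSP features of one epoch (all band variants)
#'
#' Per band, class and filter: the log of the filtered projection's
#' variance share within its projection block. Normalizing by the block sum
#' makes the features invariant to epoch-wide gain.
#'
#' @param model an `fbcsp_model`.
#' @param band_mats named list of channels x samples matrices, one per band.
#' @return numeric vector, `bands * classes * n_filters` features (named).
#' @export
fbcsp_transform <- function(model, band_mats) {
  out <- numeric(0)
  for (band in model$bands) {
    X <- center_rows(band_mats[[band]])
    for (k in model$classes) {
      P <- t(model$filters[[band]][[k]]) %*% X
      v <- apply(P, 1, stats::var)
      if (any(v == 0)) stop("zero-variance CSP projection in band ", band)
      f <- log(v / sum(v))
      names(f) <- paste0("fbcsp_", band, "_", k, "_f",
                         seq_len(model$n_filters))
      out <- c(out, f)
    }
  }
  out
}

#' Fit the full spatial-filter feature bank
#'
#' DCPM and TRCA on the low-frequency branch, FBCSP on the filter bank.
#'
#' @param fep `feature_epochs` of the training trials.
#' @param n_dsp,n_trca,n_csp dimensions kept per method.
#' @param shrinkage scalar shrinkage for all covariance estimates.
#' @return `spatial_filter_model` with `dcpm`, `trca`, `csp` sub-models.
#' @export
fit_feature_models <- function(fep, n_dsp = 2, n_trca = 3, n_csp = 3,
                               shrinkage = 0.05) {
  structure(list(dcpm = fit_dcpm(fep$mrcp, n_dsp, shrinkage),
                 trca = fit_trca(fep$mrcp, n_trca, shrinkage),
                 csp = fit_fbcsp(fep$bands, n_csp, shrinkage),
                 band_defs = fep$band_defs),
            class = "spatial_filter_model")
}

#' Per-trial feature matrix
#'
#' Concatenates the DCPM, TRCA and FBCSP features of every trial in the
#' order `[DCPM | TRCA | FBCSP]`; with the default configuration this is
#' the 56-wide feature vector (16 + 4 + 36).
#'
#' @param models a `spatial_filter_model` (fitted on training trials only).
#' @param fep `feature_epochs` of the trials to transform.
#' @return `feature_matrix`: `values` (trials x features, named columns),
#'   `labels`.
#' @export
extract_features <- function(models, fep) {
  if (!inherits(models, "spatial_filter_model"))
    stop("models must come from fit_feature_models()")
  n <- length(fep$labels)
  rows <- lapply(seq_len(n), function(i) {
    band_mats <- lapply(fep$bands, function(ep) epoch_mat(ep, i))
    c(dcpm_transform(models$dcpm, epoch_mat(fep$mrcp, i)),
      trca_transform(models$trca, epoch_mat(fep$mrcp, i)),
      fbcsp_transform(models$csp, band_mats))
  })
  values <- do.call(rbind, rows)
  structure(list(values = values, labels = fep$labels),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("<feature_matrix> ", nrow(x$values), " trials x ", ncol(x$values),
      " features\n", sep = "")
  invisible(x)
}
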