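#' Decoder configuration
#'
#' @param C linear-SVM penalty (default 1, the value used throughout).
#' @param folds cross-validation folds (default 10).
#' @param k_features features kept by mutual-information selection
#'   (default 10, the online setting; swept offline).
#' @param n_bins histogram bins per feature for the MI estimator.
#' @param seed seed for fold shuffling.
#' @return named list of class `decoder_config`.
#' @export
decoder_config <- function(C = 1, folds = 10, k_features = 10, n_bins = 10,
                           seed = 1) {
  if (C <= 0) stop("C must be positive")
  if (folds < 2) stop("folds must be >= 2")
  structure(list(C = C, folds = folds, k_features = k_features,
                 n_bins = n_bins, seed = seed), class = "decoder_config")
}

# exact discrete MI (bits) from a joint count table
mi_from_table <- function(tab) {
  p <- tab / sum(tab)
  px <- rowSums(p); py <- colSums(p)
  nz <- p > 0
  sum(p[nz] * log2(p[nz] / outer(px, py)[nz]))
}

#' Mutual-information feature ranking
#'
#' Each feature is discretized into `n_bins` equal-width bins over its
#' observed range; the mutual information with the class label (in bits) is
#' computed from the joint histogram. Constant features score 0. The
#' ranking is by descending score with ties broken by ascending feature
#' index.
#'
#' @param features `feature_matrix` or plain trials x features matrix
#'   (training rows only — selection must never see test data).
#' @param labels class labels (ignored when `features` carries its own).
#' @param n_bins bins per feature (>= 2).
#' @return `selection_result`: `mi_scores` (bits), `ranking`, `binning`.
#' @export
mutual_information_rank <- function(features, labels = NULL, n_bins = 10) {
  if (inherits(features, "feature_matrix")) {
    labels <- features$labels
    features <- features$values
  }
  features <- as.matrix(features)
  if (n_bins < 2) stop("n_bins must be >= 2")
  if (length(unique(labels)) < 2) stop("need >= 2 classes")
  y <- factor(labels)
  scores <- vapply(seq_len(ncol(features)), function(j) {
    x <- features[, j]
    rng <- range(x)
    if (diff(rng) == 0) return(0)
    breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
    bin <- cut(x, breaks, include.lowest = TRUE)
    mi_from_table(table(bin, y))
  }, numeric(1))
  names(scores) <- colnames(features)
  ranking <- order(-scores, seq_along(scores))
  structure(list(mi_scores = scores, ranking = ranking, binning = n_bins),
            class = "selection_result")
}

#' Top-k selected feature indices
#' @param selection a `selection_result`.
#' @param k number of features, `1 <= k <= length(ranking)`.
#' @return integer vector of k feature indices.
#' @export
select_top_k <- function(selection, k) {
  if (k < 1 || k > length(selection$ranking))
    stop("k must lie in [1, ", length(selection$ranking), "]")
  selection$ranking[seq_len(k)]
}

# seeded stratified fold assignment; guards per-class counts
stratified_folds <- function(labels, folds, seed) {
  y <- factor(labels)
  if (any(table(y) < folds))
    stop("every class needs at least as many trials as folds")
  set.seed(seed)
  fold <- integer(length(labels))
  for (k in levels(y)) {
    idx <- sample(which(y == k))
    fold[idx] <- rep_len(seq_len(folds), length(idx))
  }
  fold
}

# z-scoring by train statistics; zero-sd features left unscaled
fit_scaler <- function(train) {
  mu <- colMeans(train)
  sd_ <- apply(train, 2, stats::sd)
  sd_[sd_ == 0] <- 1
  list(mu = mu, sd = sd_)
}
apply_scaler <- function(scaler, m) sweep(sweep(m, 2, scaler$mu), 2, scaler$sd, "/")

train_svm <- function(x, y, C) {
  e1071::svm(x = x, y = factor(y), kernel = "linear", cost = C,
             scale = FALSE)
}

build_report <- function(truth, pred, classes, fold = NULL,
                         selected = NULL) {
  truth <- factor(truth, levels = classes)
  pred <- factor(pred, levels = classes)
  confusion <- table(true = truth, predicted = pred)
  fold_acc <- if (!is.null(fold)) {
    vapply(sort(unique(fold)), function(f)
      100 * mean(pred[fold == f] == truth[fold == f]), numeric(1))
  } else NULL
  structure(list(fold_accuracies = fold_acc,
                 mean_accuracy = 100 * sum(diag(confusion)) / sum(confusion),
                 confusion = confusion, classes = classes,
                 selected_features = selected,
                 decisions = data.frame(true = as.character(truth),
                                        predicted = as.character(pred),
                                        stringsAsFactors = FALSE)),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat("<classification_report> mean accuracy ",
      sprintf("%.2f%%", x$mean_accuracy), " over ",
      nrow(x$decisions), " trials (", length(x$classes), " classes)\n",
      sep = "")
  invisible(x)
}

#' Cross-validated decoding of a feature matrix
#'
#' Stratified k-fold cross-validation. Within each fold, MI ranking,
#' top-k selection and feature standardization are fitted on the training
#' split only, then a linear SVM (libsvm, one-vs-one for multiclass) is
#' trained and the held-out trials predicted. Predictions are pooled into
#' one confusion matrix; the mean accuracy is its trace over the total.
#'
#' @param features `feature_matrix` (or matrix with `labels` given).
#' @param labels class labels when `features` is a plain matrix.
#' @param config a [decoder_config()].
#' @return a `classification_report`.
#' @export
crossvalidate <- function(features, labels = NULL,
                          config = decoder_config()) {
  if (inherits(features, "feature_matrix")) {
    labels <- features$labels
    features <- features$values
  }
  classes <- sort(unique(labels))
  fold <- stratified_folds(labels, config$folds, config$seed)
  pred <- character(length(labels))
  selected <- list()
  for (f in seq_len(config$folds)) {
    tr <- fold != f; te <- fold == f
    sel <- select_top_k(
      mutual_information_rank(features[tr, , drop = FALSE], labels[tr],
                              config$n_bins),
      min(config$k_features, ncol(features)))
    scaler <- fit_scaler(features[tr, sel, drop = FALSE])
    xtr <- apply_scaler(scaler, features[tr, sel, drop = FALSE])
    xte <- apply_scaler(scaler, features[te, sel, drop = FALSE])
    fit <- train_svm(xtr, labels[tr], config$C)
    pred[te] <- as.character(stats::predict(fit, xte))
    selected[[f]] <- sel
  }
  build_report(labels, pred, classes, fold = fold, selected = selected)
}

#' Cross-validated decoding from epochs (leakage-free end to end)
#'
#' As [crossvalidate()], but the spatial-filter models (DCPM, TRCA, FBCSP)
#' are also refitted inside every fold on the training trials only, so no
#' stage of the pipeline ever sees a test label or test trial.
#'
#' @param fep `feature_epochs` for all trials.
#' @param config a [decoder_config()].
#' @param shrinkage covariance shrinkage passed to the model fits.
#' @return a `classification_report`.
#' @export
pipeline_crossvalidate <- function(fep, config = decoder_config(),
                                   shrinkage = 0.05) {
  labels <- fep$labels
  classes <- sort(unique(labels))
  fold <- stratified_folds(labels, config$folds, config$seed)
  pred <- character(length(labels))
  selected <- list()
  for (f in seq_len(config$folds)) {
    tr_idx <- which(fold != f); te_idx <- which(fold == f)
    models <- fit_feature_models(fep_subset(fep, tr_idx),
                                 shrinkage = shrinkage)
    ftr <- extract_features(models, fep_subset(fep, tr_idx))
    fte <- extract_features(models, fep_subset(fep, te_idx))
    sel <- select_top_k(
      mutual_information_rank(ftr, n_bins = config$n_bins),
      min(config$k_features, ncol(ftr$values)))
    scaler <- fit_scaler(ftr$values[, sel, drop = FALSE])
    xtr <- apply_scaler(scaler, ftr$values[, sel, drop = FALSE])
    xte <- apply_scaler(scaler, fte$values[, sel, drop = FALSE])
    fit <- train_svm(xtr, labels[tr_idx], config$C)
    pred[te_idx] <- as.character(stats::predict(fit, xte))
    selected[[f]] <- sel
  }
  build_report(labels, pred, classes, fold = fold, selected = selected)
}

#' Nested cross-validation over the number of selected features
#'
#' The outer loop reports an unbiased accuracy: within each outer training
#' split, an inner cross-validation scores every `k` in `k_grid`, the best
#' inner `k` is chosen (ties to the smaller k), and the outer test fold is
#' predicted at that k.
#'
#' @param features `feature_matrix` or matrix.
#' @param labels labels when `features` is a matrix.
#' @param config a [decoder_config()]; `folds` drives the outer loop.
#' @param k_grid candidate feature counts.
#' @param inner_folds folds of the inner loop.
#' @return list: `best_k` (most frequently chosen), `curve` (data.frame
#'   `k`, `inner_accuracy`), `outer_accuracy` (%), `chosen_k` per fold.
#' @export
sweep_feature_count <- function(features, labels = NULL,
                                config = decoder_config(),
                                k_grid = c(seq(5, 55, by = 5), 56),
                                inner_folds = 5) {
  if (inherits(features, "feature_matrix")) {
    labels <- features$labels
    features <- features$values
  }
  if (any(k_grid < 1 | k_grid > ncol(features)))
    stop("k_grid must lie within [1, ", ncol(features), "]")
  classes <- sort(unique(labels))
  fold <- stratified_folds(labels, config$folds, config$seed)
  pred <- character(length(labels))
  chosen <- integer(config$folds)
  inner_curves <- matrix(0, config$folds, length(k_grid))
  for (f in seq_len(config$folds)) {
    tr <- which(fold != f); te <- which(fold == f)
    inner_cfg <- decoder_config(C = config$C, folds = inner_folds,
                                n_bins = config$n_bins,
                                seed = config$seed + f)
    accs <- vapply(k_grid, function(k) {
      cfg <- inner_cfg; cfg$k_features <- k
      crossvalidate(features[tr, , drop = FALSE], labels[tr], cfg)$mean_accuracy
    }, numeric(1))
    inner_curves[f, ] <- accs
    k_best <- k_grid[which.max(accs)]
    chosen[f] <- k_best
    sel <- select_top_k(
      mutual_information_rank(features[tr, , drop = FALSE], labels[tr],
                              config$n_bins), k_best)
    scaler <- fit_scaler(features[tr, sel, drop = FALSE])
    fit <- train_svm(apply_scaler(scaler, features[tr, sel, drop = FALSE]),
                     labels[tr], config$C)
    pred[te] <- as.character(stats::predict(
      fit, apply_scaler(scaler, features[te, sel, drop = FALSE])))
  }
  report <- build_report(labels, pred, classes, fold = fold)
  list(best_k = as.integer(names(which.max(table(chosen)))),
       curve = data.frame(k = k_grid,
                          inner_accuracy = colMeans(inner_curves)),
       outer_accuracy = report$mean_accuracy,
       chosen_k = chosen, report = report)
}

#' Simulated online session
#'
#' Mirrors the online protocol: all spatial-filter models, the MI selection
#' (k = 10 by default) and two binary linear SVMs (LL-vs-RR, LR-vs-RL) are
#' fitted once on the trials of blocks 1-6; block 7 trials are then
#' classified LL-vs-RR and block 8 trials LR-vs-RL. Test trials never enter
#' any fitting step.
#'
#' @param fep `feature_epochs` of the whole online session.
#' @param blocks per-trial block number (1-8).
#' @param config a [decoder_config()]; `k_features` defaults to 10.
#' @param shrinkage covariance shrinkage for the model fits.
#' @return list of two `classification_report`s: `ll_rr` (block 7),
#'   `lr_rl` (block 8).
#' @export
simulate_online <- function(fep, blocks, config = decoder_config(),
                            shrinkage = 0.05) {
  if (length(blocks) != length(fep$labels))
    stop("blocks must have one entry per trial")
  if (!all(1:8 %in% blocks))
    stop("online data must contain blocks 1-8")
  train_idx <- which(blocks <= 6)
  models <- fit_feature_models(fep_subset(fep, train_idx),
                               shrinkage = shrinkage)
  f_train <- extract_features(models, fep_subset(fep, train_idx))
  out <- list()
  specs <- list(ll_rr = list(pair = c("LL", "RR"), block = 7),
                lr_rl = list(pair = c("LR", "RL"), block = 8))
  for (nm in names(specs)) {
    pair <- specs[[nm]]$pair
    rows <- which(f_train$labels %in% pair)
    sel <- select_top_k(
      mutual_information_rank(f_train$values[rows, , drop = FALSE],
                              f_train$labels[rows], config$n_bins),
      min(config$k_features, ncol(f_train$values)))
    scaler <- fit_scaler(f_train$values[rows, sel, drop = FALSE])
    fit <- train_svm(
      apply_scaler(scaler, f_train$values[rows, sel, drop = FALSE]),
      f_train$labels[rows], config$C)
    te_idx <- which(blocks == specs[[nm]]$block)
    f_test <- extract_features(models, fep_subset(fep, te_idx))
    pred <- as.character(stats::predict(
      fit, apply_scaler(scaler, f_test$values[, sel, drop = FALSE])))
    out[[nm]] <- build_report(f_test$labels, pred, pair,
                              selected = list(sel))
  }
  out
}

#' Keystroke interval statistics per task
#'
#' Descriptive statistics of the keystroke-1 to keystroke-2 interval per
#' task over the retained trials, with a one-way test across tasks
#' (Welch's ANOVA, reported by name).
#'
#' @param rec an [eeg_recording] with trial events.
#' @return data.frame `task`, `n`, `mean`, `sd` (seconds); attributes
#'   `test` (htest) and `test_name`.
#' @export
keystroke_interval_stats <- function(rec) {
  trials <- split_trials(rec$events)
  rows <- lapply(trials, function(tr) {
    keys <- tr$sample[tr$code %in% c("KEY_LEFT", "KEY_RIGHT")]
    if (length(keys) != 2) return(NULL)
    data.frame(task = tr$task[1], gap = (keys[2] - keys[1]) / rec$rate,
               stringsAsFactors = FALSE)
  })
  d <- do.call(rbind, rows)
  if (is.null(d) || nrow(d) == 0) stop("no complete trials")
  stats_df <- do.call(rbind, lapply(split(d, d$task), function(g)
    data.frame(task = g$task[1], n = nrow(g), mean = mean(g$gap),
               sd = stats::sd(g$gap), stringsAsFactors = FALSE)))
  rownames(stats_df) <- NULL
  if (length(unique(d$task)) > 1 && all(stats_df$sd > 0, na.rm = TRUE)) {
    tst <- stats::oneway.test(gap ~ task, data = d)
    attr(stats_df, "test") <- tst
    attr(stats_df, "test_name") <- "Welch one-way ANOVA"
  }
  stats_df
}
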