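test_that("MI matches the exact discrete oracle and handles edge cases", {
  # deterministic function of a balanced 4-class label: MI = log2(4)
  labels <- rep(TASKS, each = 50)
  x <- as.numeric(factor(labels))
  sel <- mutual_information_rank(cbind(f = x), labels)
  expect_equal(unname(sel$mi_scores[1]), 2, tolerance = 1e-12)

  # random discrete tables: histogram MI equals the exact joint-table MI
  set.seed(3)
  for (r in 1:5) {
    y <- sample(c("a", "b", "c"), 300, replace = TRUE)
    v <- sample(0:4, 300, replace = TRUE, prob = runif(5))
    ours <- mutual_information_rank(cbind(v = v), y, n_bins = 10)$mi_scores
    tab <- table(v, y)
    p <- tab / sum(tab); px <- rowSums(p); py <- colSums(p)
    nz <- p > 0
    exact <- sum(p[nz] * log2(p[nz] / outer(px, py)[nz]))
    expect_equal(unname(ours), exact, tolerance = 1e-12)
  }

  # independent feature at large n: MI below 0.05 bits
  set.seed(4)
  y2 <- sample(TASKS, 2000, replace = TRUE)
  ind <- mutual_information_rank(cbind(rnorm(2000)), y2)$mi_scores
  expect_lt(unname(ind), 0.05)

  # affine rescaling leaves MI unchanged; constant feature scores 0
  set.seed(5)
  f <- rnorm(200); y3 <- rep(c("LL", "RR"), 100)
  m1 <- mutual_information_rank(cbind(f), y3)$mi_scores
  m2 <- mutual_information_rank(cbind(3 * f - 7), y3)$mi_scores
  expect_equal(unname(m1), unname(m2), tolerance = 1e-12)
  expect_equal(unname(mutual_information_rank(cbind(rep(1, 200)),
                                              y3)$mi_scores), 0)
})

test_that("top-k selection respects ranking, bounds and tie-breaks", {
  labels <- rep(c("LL", "RR"), 60)
  x <- cbind(a = as.numeric(labels == "LL"),
             b = rnorm(120),
             c = as.numeric(labels == "LL"))   # tied with a
  sel <- mutual_information_rank(x, labels)
  expect_equal(sel$ranking[1:2], c(1L, 3L))    # tie -> lower index first
  expect_length(select_top_k(sel, 2), 2)
  expect_equal(select_top_k(sel, 3), sel$ranking)
  expect_error(select_top_k(sel, 0), "k must")
  expect_error(select_top_k(sel, 4), "k must")
})

test_that("cross-validation is perfect on separable features, chance on
           permuted labels, and bookkeeps the confusion matrix", {
  set.seed(6)
  n_per <- 40
  labels <- rep(TASKS, each = n_per)
  centers <- matrix(c(3, 0, 0, 3, -3, 0, 0, -3), 4, 2, byrow = TRUE)
  x <- centers[as.integer(factor(labels)), ] +
    matrix(rnorm(2 * length(labels), sd = 0.2), ncol = 2)
  x <- cbind(x, matrix(rnorm(10 * length(labels)), ncol = 10))
  cfg <- decoder_config(folds = 10, k_features = 5, seed = 1)
  rep <- crossvalidate(x, labels, cfg)
  expect_equal(rep$mean_accuracy, 100)
  expect_equal(as.vector(rowSums(rep$confusion)), rep(n_per, 4))
  expect_length(rep$fold_accuracies, 10)
  expect_equal(rep$mean_accuracy,
               100 * sum(diag(rep$confusion)) / sum(rep$confusion))

  perm <- crossvalidate(x, sample(labels), cfg)
  se <- 100 * sqrt(0.25 * 0.75 / length(labels))
  expect_lt(abs(perm$mean_accuracy - 25), 3 * se)

  small_lab <- rep(TASKS, 3)
  small_x <- matrix(rnorm(12 * 4), 12, 4)
  expect_error(crossvalidate(small_x, small_lab,
                             decoder_config(folds = 10)), "folds")
})

test_that("cross-validated reports are reproducible under a fixed seed", {
  set.seed(7)
  labels <- rep(TASKS, each = 12)
  x <- matrix(rnorm(48 * 8), 48, 8)
  cfg <- decoder_config(folds = 4, k_features = 4, seed = 9)
  a <- crossvalidate(x, labels, cfg)
  b <- crossvalidate(x, labels, cfg)
  expect_identical(a$decisions, b$decisions)
  expect_identical(a$confusion, b$confusion)
})

test_that("nested sweep reports a curve per k and an unbiased accuracy", {
  set.seed(8)
  labels <- rep(TASKS, each = 30)
  informative <- model.matrix(~ 0 + factor(labels)) %*%
    (3 * matrix(rnorm(8), 4))
  x <- cbind(informative + matrix(rnorm(240), ncol = 2),
             matrix(rnorm(120 * 20), ncol = 20))
  colnames(x) <- paste0("f", seq_len(ncol(x)))
  cfg <- decoder_config(folds = 4, seed = 2)
  sw <- sweep_feature_count(x, labels, cfg, k_grid = c(2, 5, 10, 20),
                            inner_folds = 3)
  expect_equal(nrow(sw$curve), 4)
  expect_true(sw$best_k %in% c(2, 5, 10, 20))
  expect_gte(sw$best_k, 2)                  # >= number of informative dims
  expect_true(sw$outer_accuracy > 50)
  expect_error(sweep_feature_count(x, labels, cfg, k_grid = c(1, 99)),
               "k_grid")
})

test_that("online simulation trains on blocks 1-6 only and scores 7/8", {
  # reduced online session: same block structure, fewer trials per block
  set.seed(10)
  tasks <- c(unlist(lapply(1:6, function(b) sample(rep(TASKS, 2)))),
             sample(rep(c("LL", "RR"), 4)), sample(rep(c("LR", "RL"), 4)))
  blocks <- c(rep(1:6, each = 8), rep(7L, 8), rep(8L, 8))
  sched <- seqfinger:::schedule_from_tasks(tasks, blocks, 0, 0,
                                           c(1.2, 2), 1)
  p <- signal_params(noise_scale = 2, line_amp = 0, eog_rate = 0)
  rec <- simulate_dataset(sched, p, mini_montage(), rate = 250, seed = 11)
  fep <- prepare_feature_epochs(rec)
  res <- simulate_online(fep, sched$block,
                         decoder_config(k_features = 10))
  expect_equal(nrow(res$ll_rr$decisions), 8)
  expect_setequal(unique(res$ll_rr$decisions$true), c("LL", "RR"))
  expect_equal(nrow(res$lr_rl$decisions), 8)
  expect_setequal(unique(res$lr_rl$decisions$true), c("LR", "RL"))
  expect_length(res$ll_rr$selected_features[[1]], 10)
  # near-noiseless data must be almost perfectly separable
  expect_gte(res$ll_rr$mean_accuracy, 75)
  expect_gte(res$lr_rl$mean_accuracy, 75)
  expect_error(simulate_online(fep, rep(1, length(fep$labels))), "blocks")
})

test_that("keystroke interval statistics match the generator's timing", {
  # jitter-free: every interval exactly 1 s
  rec0 <- clean_dataset(trials_per_block = 8, seed = 13)
  s0 <- keystroke_interval_stats(rec0)
  expect_equal(s0$mean, rep(1, nrow(s0)), tolerance = 1e-9)
  expect_equal(s0$sd, rep(0, nrow(s0)), tolerance = 1e-9)

  # jitter sd 0.05: pooled SD within 20% at 600 trials (events only)
  sched <- make_protocol(n_blocks = 10, trials_per_block = 60, seed = 14,
                         jitter_sd = 0.05)
  rate <- 1000
  ev <- do.call(rbind, lapply(seq_len(nrow(sched)), function(i)
    trial_events(sched$cue[i], sched$task[i], sched$key1[i], sched$key2[i],
                 rate)))
  mont <- montage("CZ", matrix(0, 1, 2))
  rec <- eeg_recording(matrix(0, 1, max(ev$sample) + 10), rate, mont, ev)
  st <- keystroke_interval_stats(rec)
  pooled_sd <- sqrt(sum((st$n - 1) * st$sd^2) / sum(st$n - 1))
  expect_lt(abs(pooled_sd - 0.05) / 0.05, 0.2)
  expect_equal(attr(st, "test_name"), "Welch one-way ANOVA")
})

test_that("across-task interval test is non-significant under the null", {
  # tasks share one interval distribution: false-positive rate ~ alpha
  rate <- 1000
  mont <- montage("CZ", matrix(0, 1, 2))
  sig <- vapply(1:20, function(s) {
    sched <- make_protocol(n_blocks = 1, trials_per_block = 60,
                           seed = 100 + s, jitter_sd = 0.05)
    ev <- do.call(rbind, lapply(seq_len(nrow(sched)), function(i)
      trial_events(sched$cue[i], sched$task[i], sched$key1[i],
                   sched$key2[i], rate)))
    rec <- eeg_recording(matrix(0, 1, max(ev$sample) + 10), rate, mont, ev)
    attr(keystroke_interval_stats(rec), "test")$p.value < 0.05
  }, logical(1))
  expect_gte(mean(!sig), 0.9)
})

test_that("end-to-end accuracy grows with generator SNR", {
  acc_at <- function(noise, seeds) {
    mean(vapply(seeds, function(s) {
      sched <- make_protocol(n_blocks = 1, trials_per_block = 40,
                             seed = 600 + s)
      rec <- simulate_dataset(sched, signal_params(noise_scale = noise),
                              mini_montage(), rate = 250, seed = 700 + s)
      fep <- prepare_feature_epochs(rec)
      pipeline_crossvalidate(fep, decoder_config(folds = 4, k_features = 10,
                                                 seed = s))$mean_accuracy
    }, numeric(1)))
  }
  # noise levels straddle the transition from chance to high accuracy at
  # this trial count (40 trials, 4 folds)
  seeds <- 1:5
  accs <- c(high_noise = acc_at(12, seeds), mid_noise = acc_at(5, seeds),
            low_noise = acc_at(3, seeds))
  expect_true(all(diff(accs) >= 0))
  expect_gt(accs["low_noise"], accs["high_noise"])
})

test_that("nested selection is no more optimistic than leaky selection", {
  # pure-noise features: selecting on all rows before CV leaks and
  # inflates accuracy; the nested estimate must not exceed it on average
  naive_minus_nested <- vapply(1:3, function(s) {
    set.seed(800 + s)
    labels <- rep(TASKS, each = 20)
    x <- matrix(rnorm(80 * 30), 80, 30)
    colnames(x) <- paste0("f", 1:30)
    cfg <- decoder_config(folds = 4, k_features = 5, seed = s)
    leak_sel <- select_top_k(mutual_information_rank(x, labels), 5)
    naive <- crossvalidate(x[, leak_sel], labels,
                           decoder_config(folds = 4, k_features = 5,
                                          seed = s))$mean_accuracy
    nested <- sweep_feature_count(x, labels, cfg, k_grid = c(5, 10),
                                  inner_folds = 3)$outer_accuracy
    naive - nested
  }, numeric(1))
  expect_gte(mean(naive_minus_nested), 0)
})
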