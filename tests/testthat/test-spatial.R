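test_that("geigen_sym matches the brute-force oracle on small toys", {
  for (seed in 1:5) {
    n <- sample(3:8, 1)
    A <- random_spd(n, seed); B <- random_spd(n, seed + 100)
    ours <- geigen_sym(A, B)
    ref <- brute_geigen(A, B)
    expect_equal(ours$values, ref$values, tolerance = 1e-8)
    for (j in seq_len(n)) {
      v <- ours$vectors[, j]; w <- ref$vectors[, j]
      expect_gt(abs(sum(v * w)) / sqrt(sum(v^2) * sum(w^2)), 1 - 1e-8)
    }
    # eigenvector sign convention: largest-magnitude coefficient positive
    for (j in seq_len(n))
      expect_gt(ours$vectors[which.max(abs(ours$vectors[, j])), j], 0)
  }
  expect_error(geigen_sym(diag(2), matrix(c(1, 2, 2, 1), 2)), "definite")
})

test_that("CSP pair solves the two-channel toy in closed form", {
  res <- csp_pair(diag(c(4, 1)), diag(c(1, 1)), n_filters = 1)
  expect_equal(res$values, c(4 / 5, 1 / 2), tolerance = 1e-12)
  expect_equal(abs(res$filters[, 1] / sqrt(sum(res$filters[, 1]^2))),
               c(1, 0), tolerance = 1e-12)
  # equal covariances: all eigenvalues 1/2, no discriminative direction
  eq <- csp_pair(diag(3), diag(3), n_filters = 1)
  expect_equal(eq$values, rep(1 / 2, 3), tolerance = 1e-12)
  # eigenvalues always lie in (0, 1) for SPD inputs
  C1 <- random_spd(6, 7); C2 <- random_spd(6, 8)
  expect_true(all(csp_pair(C1, C2, 1)$values > 0 &
                    csp_pair(C1, C2, 1)$values < 1))
})

test_that("DSP recovers a known discriminative spatial direction", {
  set.seed(11)
  n_ch <- 6; n_t <- 100; n_tr <- 20
  dir <- c(1, -1, 0.5, 0, 0, 0); dir <- dir / sqrt(sum(dir^2))
  bump <- sin(pi * seq_len(n_t) / n_t)
  dat <- array(rnorm(2 * n_tr * n_ch * n_t, sd = 0.01),
               dim = c(2 * n_tr, n_ch, n_t))
  labels <- rep(c("LL", "RR"), each = n_tr)
  for (i in which(labels == "LL"))
    dat[i, , ] <- dat[i, , ] + dir %o% bump
  ep <- eeg_epochs(dat, labels, 0, n_t / 200, 200, paste0("ch", 1:n_ch))
  m <- fit_dcpm(ep, shrinkage = 0.01)
  w <- m$filters$LL[, 1]
  expect_gt(abs(sum(w * dir)) / sqrt(sum(w^2)), 0.99)
  # identical class means: between-class scatter 0, leading eigenvalue ~ 0
  noise <- array(rnorm(2 * n_tr * n_ch * n_t, sd = 0.2),
                 dim = c(2 * n_tr, n_ch, n_t))
  for (k in c("LL", "RR")) {               # force class means exactly equal
    idx <- which(labels == k)
    cm <- apply(noise[idx, , , drop = FALSE], c(2, 3), mean)
    for (i in idx) noise[i, , ] <- noise[i, , ] - cm + dir %o% bump
  }
  ep0 <- eeg_epochs(noise, labels, 0, n_t / 200, 200, paste0("ch", 1:n_ch))
  m0 <- fit_dcpm(ep0, shrinkage = 0.01)
  expect_lt(m0$eigenvalues$LL[1], 1e-8)
})

test_that("DCPM holds one template per class and emits 16 features", {
  rec <- clean_dataset(trials_per_block = 8, seed = 51)
  fep <- prepare_feature_epochs(rec)
  m <- fit_dcpm(fep$mrcp)
  expect_length(m$templates, 4)
  for (k in TASKS) expect_equal(dim(m$templates[[k]]), c(2, 400))
  f <- dcpm_transform(m, seqfinger:::epoch_mat(fep$mrcp, 1))
  expect_length(f, 16)
  expect_false(anyDuplicated(names(f)) > 0)
})

test_that("transforming a class's own template gives unit similarity", {
  rec <- clean_dataset(trials_per_block = 8, seed = 52)
  fep <- prepare_feature_epochs(rec)
  m <- fit_dcpm(fep$mrcp)
  # re-project the class-mean epoch: with zero noise it IS the template
  idx <- which(fep$labels == "LL")
  mean_ep <- apply(fep$mrcp$data[idx, , , drop = FALSE], c(2, 3), mean)
  f <- dcpm_transform(m, mean_ep)
  expect_equal(unname(f[c("dcpm_LL_cor1", "dcpm_LL_cor2",
                          "dcpm_LL_cca1", "dcpm_LL_cca2")]),
               rep(1, 4), tolerance = 1e-6)
})

test_that("TRCA recovers a shared component and scores its class highest", {
  set.seed(12)
  n_ch <- 6; n_t <- 120; n_tr <- 50
  dir <- c(0.8, 0.2, -0.5, 0.1, 0, 0.3); dir <- dir / sqrt(sum(dir^2))
  shared <- sin(2 * pi * 3 * seq_len(n_t) / 200)
  dat <- array(0, dim = c(n_tr, n_ch, n_t))
  for (i in seq_len(n_tr))
    dat[i, , ] <- dir %o% shared + matrix(rnorm(n_ch * n_t, sd = 0.5),
                                          n_ch, n_t)
  ep <- eeg_epochs(dat, rep("LL", n_tr), 0, n_t / 200, 200,
                   paste0("ch", 1:n_ch))
  m <- fit_trca(ep, shrinkage = 0.01)
  w <- m$filters$LL[, 1]
  # the leading filter's projection recovers the shared time course
  expect_gt(abs(cor(as.numeric(w %*% dat[1, , ]), shared)), 0.8)
  expect_gt(abs(sum(w * dir)) / sqrt(sum(w^2)), 0.95)

  # identical trials: projected template correlates 1 with any trial
  same <- dat
  for (i in seq_len(n_tr)) same[i, , ] <- dir %o% shared
  ep2 <- eeg_epochs(same, rep("LL", n_tr), 0, n_t / 200, 200,
                    paste0("ch", 1:n_ch))
  m2 <- fit_trca(ep2, shrinkage = 0.05)
  f2 <- trca_transform(m2, same[1, , ])
  expect_equal(unname(f2["trca_LL"]), 1, tolerance = 1e-9)
})

test_that("TRCA model holds 4 classes x 3 components; transform gives 4", {
  rec <- clean_dataset(trials_per_block = 8, seed = 53)
  fep <- prepare_feature_epochs(rec)
  m <- fit_trca(fep$mrcp)
  expect_length(m$filters, 4)
  for (k in TASKS) expect_equal(ncol(m$filters[[k]]), 3)
  f <- trca_transform(m, seqfinger:::epoch_mat(fep$mrcp, 1))
  expect_length(f, 4)
  # the true class's template correlation beats the others on clean data
  expect_equal(names(which.max(f)), paste0("trca_", fep$labels[1]))
})

test_that("FBCSP holds 4 classes x 3 bands x 3 filters and emits 36", {
  rec <- noisy_dataset(trials_per_block = 16, seed = 54)
  fep <- prepare_feature_epochs(rec)
  m <- fit_fbcsp(fep$bands)
  expect_length(m$filters, 3)
  for (b in names(m$filters)) {
    expect_length(m$filters[[b]], 4)
    for (k in TASKS) expect_equal(ncol(m$filters[[b]][[k]]), 3)
  }
  mats <- lapply(fep$bands, function(ep) seqfinger:::epoch_mat(ep, 1))
  f <- fbcsp_transform(m, mats)
  expect_length(f, 36)
  # normalized log-variance shares are invariant to epoch gain
  f2 <- fbcsp_transform(m, lapply(mats, function(x) 7.3 * x))
  expect_equal(f, f2, tolerance = 1e-12)
})

test_that("the assembled feature matrix is 56 wide, ordered and stable", {
  rec <- noisy_dataset(trials_per_block = 16, seed = 55)
  fep <- prepare_feature_epochs(rec)
  expect_equal(dim(fep$mrcp$data)[3], 400)      # [-0.5, 1.5) at 200 Hz
  models <- fit_feature_models(fep)
  fm <- extract_features(models, fep)
  expect_equal(ncol(fm$values), 56)
  expect_equal(sum(startsWith(colnames(fm$values), "dcpm_")), 16)
  expect_equal(sum(startsWith(colnames(fm$values), "trca_")), 4)
  expect_equal(sum(startsWith(colnames(fm$values), "fbcsp_")), 36)
  expect_equal(fm$labels, fep$labels)           # trial order preserved
  # refit with the same inputs reproduces the matrix bit-identically
  fm2 <- extract_features(fit_feature_models(fep), fep)
  expect_identical(fm$values, fm2$values)
})

test_that("features are invariant to a consistent channel reordering", {
  rec <- noisy_dataset(trials_per_block = 8, seed = 56)
  fep <- prepare_feature_epochs(rec)
  perm <- sample(length(fep$mrcp$channels))
  permute <- function(ep) {
    eeg_epochs(ep$data[, perm, , drop = FALSE], ep$labels, ep$tmin, ep$tmax,
               ep$rate, ep$channels[perm])
  }
  fep_p <- fep
  fep_p$mrcp <- permute(fep$mrcp)
  fep_p$bands <- lapply(fep$bands, permute)
  f1 <- extract_features(fit_feature_models(fep), fep)
  f2 <- extract_features(fit_feature_models(fep_p), fep_p)
  expect_equal(f1$values, f2$values, tolerance = 1e-6)
})

test_that("the low-frequency branch attenuates a 20 Hz probe by > 20 dB", {
  rate <- 200
  tt <- seq(0, 10 - 1 / rate, by = 1 / rate)
  rec <- signal_recording(list(sin(2 * pi * 20 * tt)), rate)
  out <- butterworth_filter(rec, low = 1, high = 8)
  mid <- 401:1600
  expect_lt(20 * log10(sqrt(2 * mean(out$data[1, mid]^2))), -20)
})
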