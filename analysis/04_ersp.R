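#!/usr/bin/env Rscript
# Step 4 — time-frequency (ERSP) analysis.
#
# For every cleaned offline recording: 200 Hz / CAR / 4-30 Hz epochs with
# STFT padding, Hanning-256 ERSP with the (-1.5, -1.0) s baseline. Writes
# per-task time-frequency tables for C3, Cz and C4 (averaged over
# subjects) and the 8-13 Hz band topography for the two sub-action
# windows.

suppressPackageStartupMessages(library(seqfinger))

sessions <- utils::read.table("results/01_sessions.tsv", header = TRUE,
                              sep = "\t")
subs <- sessions$subject[sessions$session == "offline"]

acc <- list()    # task -> running sum of value arrays over subjects
topo_acc <- list()
for (s in subs) {
  rec <- load_recording(sprintf("results/data/sub%02d_clean.edf", s))
  maps <- compute_ersp(ersp_pipeline(rec))
  topo <- band_topography(maps)
  topo$subject <- s
  topo_acc[[length(topo_acc) + 1]] <- topo
  for (task in names(maps)) {
    if (is.null(acc[[task]])) {
      acc[[task]] <- maps[[task]]
      acc[[task]]$n <- 1
    } else {
      acc[[task]]$values <- acc[[task]]$values + maps[[task]]$values
      acc[[task]]$n <- acc[[task]]$n + 1
    }
  }
  message("subject ", s, " done")
}

tf_rows <- list()
for (task in names(acc)) {
  m <- acc[[task]]
  vals <- m$values / m$n
  for (ch in c("C3", "CZ", "C4")) {
    ci <- which(m$channels == ch)
    grid <- expand.grid(freq = m$freqs, time = m$times)
    tf_rows[[length(tf_rows) + 1]] <- data.frame(
      task = task, channel = ch, freq = grid$freq, time = grid$time,
      ersp_db = as.vector(vals[ci, , ]))
  }
}
utils::write.table(do.call(rbind, tf_rows), "results/04_ersp_tf.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)

topo_all <- do.call(rbind, topo_acc)
topo_mean <- stats::aggregate(value ~ task + window_start + window_end +
                                channel, data = topo_all, FUN = mean)
utils::write.table(topo_mean, "results/04_ersp_topography.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

for (task in names(acc)) {
  m <- acc[[task]]
  fi <- m$freqs >= 8 & m$freqs <= 13
  ti <- m$times >= -0.5 & m$times <= 0.5
  v <- m$values / m$n
  message(sprintf("%s: first-keystroke alpha ERSP C3 %6.2f dB, C4 %6.2f dB",
                  task, mean(v[which(m$channels == "C3"), fi, ti]),
                  mean(v[which(m$channels == "C4"), fi, ti])))
}
message("wrote results/04_ersp_{tf,topography}.tsv")
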