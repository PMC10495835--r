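#!/usr/bin/env Rscript
# Step 3 — MRCP waveform analysis.
#
# For every cleaned offline recording: 16 Hz / 3 Hz low-pass / CAR epochs
# [-2, 3) s around the first keystroke. Writes: per-task grand-average
# waveforms at C3 and C4, pointwise paired-t masks contrasting the
# repeated-finger vs different-finger tasks across subjects, and the
# -150 / 850 ms topography table.

suppressPackageStartupMessages(library(seqfinger))

abind_trials <- function(a, b) {
  stopifnot(all(dim(a)[2:3] == dim(b)[2:3]))
  out <- array(0, dim = c(dim(a)[1] + dim(b)[1], dim(a)[2], dim(a)[3]))
  out[seq_len(dim(a)[1]), , ] <- a
  out[dim(a)[1] + seq_len(dim(b)[1]), , ] <- b
  out
}

sessions <- utils::read.table("results/01_sessions.tsv", header = TRUE,
                              sep = "\t")
subs <- sessions$subject[sessions$session == "offline"]

all_epochs <- NULL; subject_of <- c()
waveforms <- list()
for (s in subs) {
  rec <- load_recording(sprintf("results/data/sub%02d_clean.edf", s))
  ep <- mrcp_pipeline(rec)
  if (is.null(all_epochs)) {
    all_epochs <- ep
  } else {
    all_epochs$data <- abind_trials(all_epochs$data, ep$data)
    all_epochs$labels <- c(all_epochs$labels, ep$labels)
  }
  subject_of <- c(subject_of, rep(s, length(ep$labels)))
}

ga <- grand_average(all_epochs, subjects = subject_of)
tt <- ga$times
c3 <- which(ga$channels == "C3"); c4 <- which(ga$channels == "C4")

wave_rows <- do.call(rbind, lapply(names(ga$waveforms), function(task)
  rbind(data.frame(time = tt, task = task, channel = "C3",
                   microvolts = ga$waveforms[[task]][c3, ]),
        data.frame(time = tt, task = task, channel = "C4",
                   microvolts = ga$waveforms[[task]][c4, ]))))
utils::write.table(wave_rows, "results/03_mrcp_waveforms.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

# paired-t contrasts on subject means at C3/C4, repeated vs different tasks
contrasts <- list(c("LL", "LR"), c("LL", "RL"), c("RR", "LR"), c("RR", "RL"))
mask_rows <- list()
for (ch in c("C3", "C4")) {
  ci <- which(ga$channels == ch)
  for (pair in contrasts) {
    a <- ga$subject_means[[pair[1]]][, ci, ]
    b <- ga$subject_means[[pair[2]]][, ci, ]
    res <- pointwise_paired_ttest(a, b)
    mask_rows[[length(mask_rows) + 1]] <- data.frame(
      channel = ch, contrast = paste(pair, collapse = "_vs_"),
      time = tt, t = res$t_values, p = res$p_values,
      significant = res$sig_mask)
  }
}
utils::write.table(do.call(rbind, mask_rows), "results/03_mrcp_ttest.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)

topo <- topography_at(ga, c(-0.150, 0.850))
utils::write.table(topo, "results/03_mrcp_topography.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

for (task in names(ga$waveforms)) {
  w <- tt >= -0.3 & tt <= 0
  message(sprintf("%s: pre-keystroke mean C3 %6.2f uV, C4 %6.2f uV",
                  task, mean(ga$waveforms[[task]][c3, w]),
                  mean(ga$waveforms[[task]][c4, w])))
}
message("wrote results/03_mrcp_{waveforms,ttest,topography}.tsv")
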