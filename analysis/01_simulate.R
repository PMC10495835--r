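#!/usr/bin/env Rscript
# Step 1 — simulate the study's recording sessions.
#
# Generates synthetic EEG for a small cohort: four offline "subjects"
# (2 blocks x 60 trials each, to keep this driver quick; the full protocol
# is 10 blocks) plus one full online session (blocks 1-8). Each recording
# is written as EDF with a tab-delimited event sidecar under results/data/,
# and a session summary table under results/.

suppressPackageStartupMessages(library(seqfinger))

out_dir <- "results/data"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

n_subjects <- 4
rate <- 250          # keeps file sizes moderate; Nyquist covers beta + line
params <- signal_params()

summary_rows <- list()
for (s in seq_len(n_subjects)) {
  sched <- make_protocol(n_blocks = 2, trials_per_block = 60, seed = 100 + s)
  rec <- simulate_dataset(sched, params, standard_montage_60(), rate = rate,
                          seed = 200 + s)
  # a few behavioural violations, as real sessions have
  rec <- inject_bad_trials(rec, fraction = 0.05, seed = 300 + s)
  path <- save_recording(rec, file.path(out_dir, sprintf("sub%02d", s)),
                         format = "edf")
  summary_rows[[s]] <- data.frame(
    subject = s, session = "offline", trials = nrow(sched),
    injected_bad = length(attr(rec, "bad_trials")), file = path)
  message("subject ", s, ": ", nrow(sched), " trials -> ", path)
}

onl <- make_online_protocol(seed = 900)
onl_rec <- simulate_dataset(onl, params, standard_montage_60(), rate = rate,
                            seed = 901)
onl_path <- save_recording(onl_rec, file.path(out_dir, "online"),
                           format = "edf")
utils::write.table(onl[, c("block", "trial", "task")],
                   file.path(out_dir, "online.blocks.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
summary_rows[[n_subjects + 1]] <- data.frame(
  subject = NA, session = "online", trials = nrow(onl),
  injected_bad = 0, file = onl_path)
message("online session: ", nrow(onl), " trials -> ", onl_path)

summary <- do.call(rbind, summary_rows)
utils::write.table(summary, "results/01_sessions.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
message("session table -> results/01_sessions.tsv")
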