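#!/usr/bin/env Rscript
# Step 2 — preprocessing and behavioural trial rejection.
#
# Loads each simulated offline recording, applies the 50 Hz notch, runs the
# behavioural rejection rule (wrong finger sequence, or keystrokes more
# than 2 s apart) and writes the kept/dropped trial table. The notched
# recordings are saved for the downstream analyses.

suppressPackageStartupMessages(library(seqfinger))

sessions <- utils::read.table("results/01_sessions.tsv", header = TRUE,
                              sep = "\t")
offline <- sessions[sessions$session == "offline", ]

rows <- list()
for (i in seq_len(nrow(offline))) {
  rec <- load_recording(offline$file[i])
  rec <- notch_filter(rec, 50)
  res <- reject_bad_trials(rec)
  s <- offline$subject[i]
  message("subject ", s, ": kept ", length(res$kept), ", dropped ",
          nrow(res$dropped))
  if (nrow(res$dropped) > 0)
    rows[[length(rows) + 1]] <- cbind(subject = s, res$dropped)
  clean <- keep_trials(rec, res$kept)
  save_recording(clean, sprintf("results/data/sub%02d_clean", s),
                 format = "edf")
}

dropped <- if (length(rows)) do.call(rbind, rows) else
  data.frame(subject = integer(0), trial = integer(0),
             task = character(0), reason = character(0))
utils::write.table(dropped, "results/02_dropped_trials.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
message("rejection table -> results/02_dropped_trials.tsv")
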