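#!/usr/bin/env Rscript
# Step 6 — simulated online session.
#
# Trains all spatial-filter models, the mutual-information selection
# (k = 10) and the two binary linear SVMs on blocks 1-6 of the online
# recording, then classifies block 7 (LL-vs-RR) and block 8 (LR-vs-RL),
# one decision per trial. Writes the per-trial decision log and a summary.

suppressPackageStartupMessages(library(seqfinger))

rec <- load_recording("results/data/online.edf")
blocks_tab <- utils::read.table("results/data/online.blocks.tsv",
                                header = TRUE, sep = "\t")

rec <- notch_filter(rec, 50)
rej <- reject_bad_trials(rec)
rec <- keep_trials(rec, rej$kept)
blocks <- blocks_tab$block[rej$kept]

fep <- prepare_feature_epochs(rec)
res <- simulate_online(fep, blocks, decoder_config(k_features = 10,
                                                   seed = 500))

dec <- rbind(cbind(classifier = "LL_vs_RR", block = 7,
                   res$ll_rr$decisions),
             cbind(classifier = "LR_vs_RL", block = 8,
                   res$lr_rl$decisions))
utils::write.table(dec, "results/06_online_decisions.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

summary <- data.frame(
  classifier = c("LL_vs_RR", "LR_vs_RL"),
  test_block = c(7, 8),
  trials = c(nrow(res$ll_rr$decisions), nrow(res$lr_rl$decisions)),
  accuracy_pct = c(res$ll_rr$mean_accuracy, res$lr_rl$mean_accuracy))
utils::write.table(summary, "results/06_online_summary.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
print(summary)
message("wrote results/06_online_{decisions,summary}.tsv")
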