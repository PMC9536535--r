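#!/usr/bin/env Rscript
# Stage 2: run the full hit-calling pipeline on the stage-1 screen and score
# recovery of the planted effects.
#
# Pipeline: batch anchoring on the empty-vector controls, replicate merging,
# per-gene median baseline, log2 effects, MAD-based expected range of
# variation, |Z| classification, and two-tier HIT calls (fold > 2 and
# |Z| > 4 for the hit tier).

suppressPackageStartupMessages(library(orfscreen))

res <- run_screen("results/screen_input/expression.tsv",
                  "results/screen_input/samples.tsv",
                  "results/screen_output",
                  config = screen_config(),
                  seed = 20260927L)

cat("\nper-ORF hit counts (top 10 by total):\n")
print(utils::head(res$counts, 10), row.names = FALSE)
cat(sprintf("range of per-ORF totals: %d to %d hits\n",
            min(res$counts$n_total), max(res$counts$n_total)))

truth <- utils::read.delim("results/screen_input/truth.tsv")
sc <- score_recovery(res$hits, truth)
recovery <- data.frame(metric = c("sensitivity", "precision", "f1",
                                  "n_truth", "n_called", "n_recovered"),
                       value = c(sc$sensitivity, sc$precision, sc$f1,
                                 sc$n_truth, sc$n_called, sc$n_recovered))
utils::write.table(recovery, "results/screen_output/recovery.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("\nrecovery of planted effects: sensitivity %.3f, precision %.3f, F1 %.3f\n",
            sc$sensitivity, sc$precision, sc$f1))
cat("note: planted effects below the 2-fold threshold are not callable by\n")
cat("design, which bounds attainable sensitivity below 1.\n")
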