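#!/usr/bin/env Rscript
# Stage 5: promoter/TF-binding interval intersection.
#
# Generic form of the shared-promoter-binding question: which factors have
# binding evidence over every promoter window in a query set. Runs on the
# bundled synthetic fixture (two calprotectin-subunit-style promoter windows
# against a 12-factor ChIP-seq-style peak panel).

suppressPackageStartupMessages(library(orfscreen))

promoters <- read_bed(system.file("extdata", "synthetic_promoters.bed",
                                  package = "orfscreen"))
peaks <- read_bed(system.file("extdata", "synthetic_tf_peaks.bed",
                              package = "orfscreen"))

cat(sprintf("%d promoter windows, %d peaks from %d factors\n",
            nrow(promoters), nrow(peaks), length(unique(peaks$name))))

both <- factors_binding_all(promoters, peaks)
dir.create("results/tfbs", recursive = TRUE, showWarnings = FALSE)
utils::write.table(data.frame(factor = both),
                   "results/tfbs/factors_binding_both.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("factors binding every promoter (%d): %s\n",
            length(both), paste(both, collapse = ", ")))

pairs <- intersect_intervals(promoters, peaks)
utils::write.table(pairs, "results/tfbs/promoter_peak_pairs.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("%d promoter-peak overlap pairs written\n", nrow(pairs)))
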