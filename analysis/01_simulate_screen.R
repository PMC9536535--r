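#!/usr/bin/env Rscript
# Stage 1: generate the study-scale synthetic screen.
#
# Design mirrors the full screen layout: 45 ORF conditions transduced in
# triplicate, organised in three batches of 15 ORFs, each batch with its own
# triplicate empty-vector controls; 12,000 genes with a log2 detection floor
# of 3; per-gene batch shifts and per-sample log2 noise; 50 planted signed
# effects per ORF with |log2 effect| between 1 and 3 (so some planted effects
# sit near the 2-fold calling threshold).

suppressPackageStartupMessages(library(orfscreen))

seed <- 20260927L
cfg <- suppressWarnings(simulation_config(
  n_genes = 12000, n_orfs = 45, replicates_per_orf = 3, n_batches = 3,
  controls_per_batch = 3, hits_per_orf = 50, effect_low = 1, effect_high = 3,
  noise_sd = 0.25, batch_sd = 0.3, seed = seed))

sim <- simulate_screen(cfg)
paths <- write_screen(sim, "results/screen_input")

cat(sprintf("simulated %d genes x %d samples (%d ORFs in %d batches, seed %d)\n",
            nrow(sim$matrix$values), ncol(sim$matrix$values),
            cfg$n_orfs, cfg$n_batches, seed))
cat(sprintf("planted %d (gene, ORF) effects; |log2 effect| in [%g, %g]\n",
            nrow(sim$truth), cfg$effect_low, cfg$effect_high))
cat("wrote:", paste(paths, collapse = ", "), "\n")
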