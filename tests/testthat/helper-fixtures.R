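# Small fixture builders used across test files.

# Condition profiles with random values spanning detected and undetected genes.
make_random_profiles <- function(n_genes, n_conds, seed, control = "CONTROL") {
  set.seed(seed)
  genes <- sprintf("g%03d", seq_len(n_genes))
  conds <- c(sprintf("ORF%02d", seq_len(n_conds - 1)), control)
  base <- runif(n_genes, 1, 10)  # some genes fall below the detection floor of 3
  vals <- matrix(base, n_genes, n_conds, dimnames = list(genes, conds)) +
    matrix(rnorm(n_genes * n_conds, 0, 0.4), n_genes, n_conds)
  # sprinkle a few strong effects so hits exist
  idx <- cbind(sample.int(n_genes, max(2, n_genes %/% 10)),
               sample.int(n_conds - 1, max(2, n_genes %/% 10), replace = TRUE))
  vals[idx] <- vals[idx] + sample(c(-3, 3), nrow(idx), replace = TRUE)
  structure(list(values = vals,
                 n_replicates = stats::setNames(rep(3L, n_conds), conds),
                 control = control),
            class = "condition_profiles")
}

# Hand-assembled effect table for direct rule tests of call_hits().
make_manual_effect_table <- function(effects, z, baseline, config = screen_config(),
                                     control = "CONTROL") {
  detected <- baseline >= config$detection_floor_log2
  cls <- classify_effects(z, detected, config)
  structure(list(baseline = baseline, effects = effects,
                 scale = abs(effects / z), z = z, detected = detected,
                 class = cls, conditions = colnames(effects),
                 control = control, config = config),
            class = "effect_table")
}

# Tiny expression matrix + sheet: 2 batches, 2 ORFs x 2 reps, 1 control each.
make_tiny_screen <- function(seed = 1) {
  set.seed(seed)
  genes <- sprintf("g%02d", 1:8)
  samples <- c("A_r1", "A_r2", "B_r1", "B_r2", "C1", "C2")
  vals <- matrix(runif(48, 4, 9), 8, 6, dimnames = list(genes, samples))
  sheet <- data.frame(
    sample = samples,
    condition = c("A", "A", "B", "B", "CONTROL", "CONTROL"),
    replicate = c(1, 2, 1, 2, 1, 1),
    batch = c("B1", "B1", "B2", "B2", "B1", "B2"),
    is_control = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE),
    stringsAsFactors = FALSE)
  list(em = expression_matrix(vals, "log2"), sheet = sheet)
}
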