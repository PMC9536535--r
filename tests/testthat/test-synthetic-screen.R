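test_that("zero-noise null screens make every ORF column equal the controls", {
  sim <- simulate_screen(simulation_config(
    n_genes = 60, n_orfs = 3, noise_sd = 0, batch_sd = 0, hits_per_orf = 0,
    seed = 11))
  v <- sim$matrix$values
  ctrl <- sim$samples$sample[sim$samples$is_control]
  for (s in sim$samples$sample[!sim$samples$is_control])
    for (cc in ctrl) expect_identical(v[, s], stats::setNames(v[, cc], rownames(v)))
  expect_identical(nrow(sim$truth), 0L)
})

test_that("planted effects are constructed exactly when noise is off", {
  cfg <- simulation_config(n_genes = 100, n_orfs = 2, hits_per_orf = 5,
                           effect_low = 2, effect_high = 2, noise_sd = 0,
                           batch_sd = 0, seed = 3)
  sim <- simulate_screen(cfg)
  v <- sim$matrix$values
  ctrl_baseline <- rowMeans(v[, sim$samples$sample[sim$samples$is_control]])
  expect_identical(nrow(sim$truth), 10L)
  expect_true(all(abs(sim$truth$effect) == 2))
  for (i in seq_len(nrow(sim$truth))) {
    reps <- sim$samples$sample[sim$samples$condition == sim$truth$condition[i]]
    measured <- mean(v[sim$truth$gene[i], reps]) -
      unname(ctrl_baseline[sim$truth$gene[i]])
    expect_equal(measured, sim$truth$effect[i], tolerance = 1e-12)
  }
})

test_that("identical seeds reproduce the screen byte for byte, different seeds do not", {
  cfg <- simulation_config(n_genes = 80, n_orfs = 3, seed = 7, hits_per_orf = 5)
  a <- simulate_screen(cfg)
  b <- simulate_screen(cfg)
  expect_identical(a$matrix$values, b$matrix$values)
  expect_identical(a$truth, b$truth)
  cfg2 <- simulation_config(n_genes = 80, n_orfs = 3, seed = 8, hits_per_orf = 5)
  expect_false(identical(a$matrix$values, simulate_screen(cfg2)$matrix$values))
})

test_that("screen dimensions, batch assignment and truth invariants hold", {
  cfg <- simulation_config(n_genes = 200, n_orfs = 7, replicates_per_orf = 4,
                           n_batches = 3, controls_per_batch = 2,
                           hits_per_orf = 10, seed = 5)
  sim <- simulate_screen(cfg)
  expect_identical(dim(sim$matrix), c(200L, 7L * 4L + 3L * 2L))
  orf_rows <- sim$samples[!sim$samples$is_control, ]
  expect_true(all(tapply(orf_rows$batch, orf_rows$condition,
                         function(b) length(unique(b))) == 1))
  expect_false(any(duplicated(sim$truth[, c("gene", "condition")])))
  expect_true(all(abs(sim$truth$effect) >= cfg$effect_low &
                  abs(sim$truth$effect) <= cfg$effect_high))
  expect_no_error(validate_screen_inputs(sim$matrix, sim$samples))
})

test_that("counts mode yields non-negative integers and is seed-deterministic", {
  cfg <- simulation_config(n_genes = 100, n_orfs = 2, output_scale = "counts",
                           baseline_log2_mean = 7, seed = 9)
  sim <- simulate_screen(cfg)
  expect_identical(sim$matrix$scale, "counts")
  expect_true(all(sim$matrix$values >= 0))
  expect_true(all(sim$matrix$values == floor(sim$matrix$values)))
  expect_identical(sim$matrix$values, simulate_screen(cfg)$matrix$values)
})

test_that("sub-threshold planted effects warn but are allowed", {
  expect_warning(simulation_config(effect_low = 0.5, effect_high = 0.8),
                 "2-fold")
  expect_error(simulation_config(n_genes = 0), "positive")
  expect_error(simulation_config(hits_per_orf = 10, n_genes = 5), "hits_per_orf")
})

test_that("score_recovery matches hand-computed sensitivity, precision and F1", {
  truth <- data.frame(gene = sprintf("g%02d", 1:10), condition = "ORF01",
                      effect = rep(c(2, -2), 5), stringsAsFactors = FALSE)
  perfect <- data.frame(condition = "ORF01", gene = truth$gene,
                        direction = ifelse(truth$effect > 0, "up", "down"),
                        tier = "hit", stringsAsFactors = FALSE)
  s <- score_recovery(perfect, truth)
  expect_identical(c(s$sensitivity, s$precision, s$f1), c(1, 1, 1))

  none <- perfect[0, ]
  s0 <- score_recovery(none, truth)
  expect_identical(s0$sensitivity, 0)
  expect_identical(s0$precision, 0)
  expect_false(s0$precision_defined)
  expect_identical(s0$f1, 0)

  # 10 called, 8 matching (2 with flipped direction): F1 = 0.8 by hand
  flipped <- perfect
  flipped$direction[1:2] <- ifelse(flipped$direction[1:2] == "up", "down", "up")
  s8 <- score_recovery(flipped, truth)
  expect_equal(s8$sensitivity, 0.8)
  expect_equal(s8$precision, 0.8)
  expect_equal(s8$f1, 0.8)

  stray <- perfect
  stray$condition[1] <- "ORF99"
  expect_error(score_recovery(stray, truth), "ORF99")
})

test_that("measured planted effects converge to truth as replicates grow", {
  dev_at <- function(reps) {
    cfg <- simulation_config(n_genes = 400, n_orfs = 3, replicates_per_orf = reps,
                             hits_per_orf = 20, noise_sd = 0.5, batch_sd = 0,
                             seed = 21)
    sim <- simulate_screen(cfg)
    v <- sim$matrix$values
    ctrl_baseline <- rowMeans(v[, sim$samples$sample[sim$samples$is_control]])
    measured <- mapply(function(g, cond) {
      reps_s <- sim$samples$sample[sim$samples$condition == cond]
      mean(v[g, reps_s]) - ctrl_baseline[g]
    }, sim$truth$gene, sim$truth$condition)
    mean(abs(measured - sim$truth$effect))
  }
  expect_lt(dev_at(30), dev_at(3))
})

test_that("recovery power rises with effect size and falls with noise", {
  sens <- function(effect, noise) {
    vals <- sapply(1:3, function(sd) {
      cfg <- suppressWarnings(simulation_config(
        n_genes = 800, n_orfs = 4, hits_per_orf = 25,
        effect_low = effect, effect_high = effect, noise_sd = noise, seed = sd))
      sim <- simulate_screen(cfg)
      res <- screen_pipeline(sim$matrix, sim$samples)
      score_recovery(res$hits, sim$truth)$sensitivity
    })
    mean(vals)
  }
  expect_gte(sens(2.5, 0.25), sens(1.2, 0.25) - 0.02)
  expect_gte(sens(2.0, 0.1), sens(2.0, 0.6) - 0.02)
})
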