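make_profiles_from <- function(values) {
  structure(list(values = values,
                 n_replicates = stats::setNames(rep(3L, ncol(values)),
                                                colnames(values)),
                 control = "CONTROL"),
            class = "condition_profiles")
}

test_that("baseline is the per-gene median across condition profiles", {
  vals <- rbind(g1 = c(4, 6, 8),
                g2 = c(5, 5, 5))
  colnames(vals) <- c("ORF01", "ORF02", "CONTROL")
  prof <- make_profiles_from(vals)
  b <- compute_baseline(prof)
  expect_equal(b[["g1"]], 6)
  expect_equal(b[["g2"]], 5)
  # all conditions equal c -> baseline c and all effects zero
  eff <- compute_effects(prof, b)
  expect_equal(unname(eff["g2", ]), c(0, 0, 0))

  # even condition count: mean of the middle two
  vals4 <- rbind(g1 = c(4, 6, 8, 100))
  colnames(vals4) <- c("ORF01", "ORF02", "ORF03", "CONTROL")
  expect_equal(compute_baseline(make_profiles_from(vals4))[["g1"]], 7)

  expect_error(compute_baseline(make_profiles_from(vals[, 1, drop = FALSE])),
               "at least two")
})

test_that("effects are log2 differences from baseline with exact fold duality", {
  vals <- rbind(g1 = c(7, 5, 6))
  colnames(vals) <- c("ORF01", "ORF02", "CONTROL")
  prof <- make_profiles_from(vals)
  eff <- compute_effects(prof, c(g1 = 6))
  expect_equal(unname(eff["g1", ]), c(1, -1, 0))
  # an effect of 1 is a fold change of 2
  expect_identical(effect_to_fc(1), 2)
  expect_identical(effect_to_fc(0), 1)
  expect_identical(effect_to_fc(-2), 0.25)
  x <- seq(-5, 5, by = 0.37)
  expect_equal(effect_to_fc(x) * effect_to_fc(-x), rep(1, length(x)),
               tolerance = 1e-12)
  expect_error(compute_effects(prof, c(other = 6)), "universe")
})

test_that("robust scale estimation matches the hand-computed MAD and engages the floor", {
  eff <- matrix(c(-0.2, -0.1, 0, 0.1, 0.2, 10), 1, 6,
                dimnames = list("g1", paste0("c", 1:6)))
  cfg <- screen_config(variance_floor = 0)
  s <- estimate_expected_variation(eff, detected = TRUE, cfg)
  # median 0.05, |dev| = (.25,.15,.05,.05,.15,9.95), MAD = 0.15, x1.4826
  expect_equal(s[["g1"]], 0.15 * 1.4826, tolerance = 1e-12)

  const <- matrix(0.3, 1, 5, dimnames = list("g1", paste0("c", 1:5)))
  s0 <- estimate_expected_variation(const, TRUE, screen_config(variance_floor = 0.1))
  expect_identical(s0[["g1"]], 0.1)

  # automatic floor: 0.25 x median scale over detected genes
  set.seed(1)
  m <- matrix(rnorm(50 * 8), 50, 8,
              dimnames = list(sprintf("g%02d", 1:50), paste0("c", 1:8)))
  m[1, ] <- 0  # constant gene
  s_auto <- estimate_expected_variation(m, rep(TRUE, 50), screen_config())
  raw <- apply(m, 1, stats::mad)
  expect_equal(s_auto[["g01"]], 0.25 * median(raw), tolerance = 1e-12)

  expect_error(estimate_expected_variation(m[, 1:2], rep(TRUE, 50), screen_config()),
               "at least 3 conditions")
})

test_that("sd-estimator recovers a unit normal scale at large n", {
  set.seed(42)
  eff <- matrix(rnorm(1e4), 1, 1e4, dimnames = list("g1", NULL))
  s <- estimate_expected_variation(eff, TRUE,
                                   screen_config(variance_estimator = "sd",
                                                 variance_floor = 0))
  expect_lt(abs(s[["g1"]] - 1), 0.05)
})

test_that("classification follows the |Z| bands and the detection floor", {
  z <- matrix(c(1.5, -4.5, 2, 4, -2.5, 0.3), 3, 2,
              dimnames = list(c("g1", "g2", "g3"), c("A", "B")))
  detected <- c(TRUE, TRUE, FALSE)
  cls <- classify_effects(z, detected, screen_config())
  expect_identical(cls["g1", "A"], "within")
  expect_identical(cls["g2", "A"], "outside")
  expect_identical(cls["g3", "A"], "below_detection")  # baseline 2.9 < floor 3
  expect_identical(cls["g1", "B"], "suggestive")       # |Z| = 4 boundary: not outside
  expect_identical(cls["g2", "B"], "suggestive")
  expect_identical(cls["g3", "B"], "below_detection")
  # |Z| = 2 boundary is still within
  expect_identical(classify_effects(matrix(2, 1, 1, dimnames = list("g", "A")),
                                    TRUE, screen_config())[1, 1], "within")
})

test_that("hit calling applies the fold AND outside-variation rule per tier", {
  effects <- matrix(c(1.5, 0.9, -1.5, 0.2,
                      0, 0, 0, 0), 4, 2,
                    dimnames = list(c("g1", "g2", "g3", "g4"), c("A", "CONTROL")))
  z <- matrix(c(4.2, 5.0, -3.0, 6.0,
                0, 0, 0, 0), 4, 2, dimnames = dimnames(effects))
  baseline <- c(g1 = 6, g2 = 6, g3 = 6, g4 = 6)
  et <- make_manual_effect_table(effects, z, baseline)
  hits <- call_hits(et)
  expect_identical(hits$gene, c("g1", "g3"))
  expect_identical(hits$tier, c("hit", "suggestive"))       # g2 fails fold <= 2
  expect_identical(hits$direction, c("up", "down"))
  expect_false("CONTROL" %in% hits$condition)

  # undetected genes never appear even with extreme effect and Z
  baseline2 <- baseline
  baseline2["g1"] <- 2.5
  et2 <- make_manual_effect_table(effects, z, baseline2)
  expect_false("g1" %in% call_hits(et2)$gene)
})

test_that("hit counts tally directions and order by total with alphabetical ties", {
  hits <- data.frame(
    condition = c("B", "B", "B", "A", "A", "C"),
    gene = sprintf("g%d", 1:6),
    direction = c("up", "down", "up", "up", "down", "up"),
    tier = c("hit", "hit", "suggestive", "hit", "hit", "hit"),
    stringsAsFactors = FALSE)
  tab <- count_hits(hits, conditions = c("A", "B", "C", "D"))
  expect_identical(tab$condition, c("A", "B", "C", "D"))  # A,B tie at 2 -> alpha
  expect_identical(tab$n_up, c(1L, 1L, 1L, 0L))
  expect_identical(tab$n_down, c(1L, 1L, 0L, 0L))
  expect_identical(tab$n_total, c(2L, 2L, 1L, 0L))
})

test_that("planted up/down splits are recovered exactly in a noise-free screen", {
  # construction mirrors a strong transcription-factor ORF with a 94 up /
  # 129 down split at large effects
  cfg <- simulation_config(n_genes = 20000, n_orfs = 5, hits_per_orf = 223,
                           effect_low = 2.5, effect_high = 3.5, noise_sd = 0,
                           batch_sd = 0, frac_undetectable = 0.05, seed = 1301)
  sim <- simulate_screen(cfg)
  truth1 <- sim$truth[sim$truth$condition == "ORF01", ]
  res <- screen_pipeline(sim$matrix, sim$samples)
  tab <- res$counts[res$counts$condition == "ORF01", ]
  expect_identical(tab$n_up, sum(truth1$effect > 0))
  expect_identical(tab$n_down, sum(truth1$effect < 0))
  expect_identical(tab$n_total, nrow(truth1))
})

test_that("ma_table is consistent with classification and round-trips to 6 decimals", {
  prof <- make_random_profiles(30, 5, seed = 17)
  et <- screen_effects(prof)
  tab <- ma_table(et)
  conds <- setdiff(et$conditions, et$control)
  expect_identical(nrow(tab), 30L * length(conds))
  lv <- sort(unique(tab$class))
  expect_identical(as.integer(table(factor(tab$class, lv))),
                   as.integer(table(factor(et$class[, conds], lv))))
  p <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(format(tab, digits = 15), p, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  back <- utils::read.delim(p)
  expect_equal(back$effect, tab$effect, tolerance = 1e-6)
  expect_equal(back$baseline, tab$baseline, tolerance = 1e-6)
  expect_error(ma_table(et, "NOPE"), "NOPE")
})

test_that("raising thresholds never adds a hit", {
  for (sd in c(31, 32, 33)) {
    prof <- make_random_profiles(60, 6, seed = sd)
    key <- function(h) paste(h$condition, h$gene, h$direction)
    base <- call_hits(screen_effects(prof, screen_config()))
    tighter_z <- call_hits(screen_effects(prof, screen_config(z_hit = 6)))
    tighter_f <- call_hits(screen_effects(prof, screen_config(fold_threshold = 3)))
    base_hits <- base[base$tier == "hit", ]
    expect_true(all(key(tighter_z[tighter_z$tier == "hit", ]) %in% key(base_hits)))
    expect_true(all(key(tighter_f[tighter_f$tier == "hit", ]) %in% key(base_hits)))
  }
})

test_that("condition order never changes baselines, scales, Z or calls", {
  prof <- make_random_profiles(40, 6, seed = 77)
  et <- screen_effects(prof)
  perm <- sample(ncol(prof$values))
  prof2 <- prof
  prof2$values <- prof$values[, perm]
  prof2$n_replicates <- prof$n_replicates[perm]
  et2 <- screen_effects(prof2)
  expect_equal(et2$baseline, et$baseline, tolerance = 1e-12)
  expect_equal(et2$scale, et$scale, tolerance = 1e-12)
  expect_equal(et2$z[, et$conditions], et$z, tolerance = 1e-12)
  h1 <- call_hits(et); h2 <- call_hits(et2)
  o <- function(h) h[order(h$condition, h$gene), c("condition", "gene", "direction", "tier")]
  expect_equal(o(h2), o(h1), ignore_attr = TRUE)
})

test_that("pipeline matches the brute-force oracle on random small screens", {
  for (sd in c(101, 102, 103, 104, 105)) {
    prof <- make_random_profiles(sample(20:60, 1), sample(4:8, 1), seed = sd)
    cfg <- screen_config()
    et <- screen_effects(prof, cfg)
    oracle <- oracle_screen(prof$values, prof$control, cfg)
    expect_equal(et$baseline, oracle$baseline, tolerance = 1e-12)
    expect_equal(et$effects, oracle$effects, tolerance = 1e-12)
    expect_equal(as.numeric(et$scale), as.numeric(oracle$scale), tolerance = 1e-12)
    expect_equal(et$z, oracle$z, tolerance = 1e-12)
    expect_identical(et$class, oracle$class)
    h <- call_hits(et)
    o <- function(d) d[order(d$condition, d$gene),
                       c("condition", "gene", "direction", "tier")]
    expect_equal(o(h), o(oracle$hits), ignore_attr = TRUE)
  }
})
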