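#' Simulation configuration for a synthetic ORF screen
#'
#' Describes a synthetic overexpression screen: ORF conditions transduced in
#' replicate and organised in batches, each batch carrying its own empty-vector
#' control samples; per-gene log2 baselines with a detection floor; additive
#' per-gene batch shifts; Gaussian log2 noise per sample; and planted per-ORF
#' effects that downstream hit calling should recover.
#'
#' @param n_genes Number of genes.
#' @param n_orfs Number of ORF conditions.
#' @param replicates_per_orf Replicate infections per ORF (default 3).
#' @param n_batches Number of experimental batches; ORFs are split across them
#'   as evenly as possible (default 3).
#' @param controls_per_batch Empty-vector control samples per batch (default 3).
#' @param baseline_log2_mean,baseline_log2_sd Normal distribution of per-gene
#'   baseline log2 expression (defaults 6 and 2).
#' @param noise_sd Per-sample additive Gaussian noise on the log2 scale
#'   (default 0.25).
#' @param batch_sd Scale of per-gene, per-batch additive shifts shared by every
#'   sample of a batch (default 0.3).
#' @param hits_per_orf Number of genes with a planted effect per ORF
#'   (default 50).
#' @param effect_low,effect_high Range of |log2 effect| for planted hits
#'   (defaults 1.5 and 3). Values >= 1 guarantee planted effects exceed the
#'   2-fold hit criterion in expectation; `effect_low < 1` is allowed with a
#'   warning to permit sub-threshold power studies.
#' @param frac_undetectable Fraction of genes forced below the detection floor
#'   (default 0.1).
#' @param detection_floor_log2 Detection floor used to place undetectable genes
#'   and to restrict planting to detectable genes (default 3).
#' @param libsize_cv Coefficient of variation of multiplicative library-size
#'   factors, applied only on the counts output scale (default 0.15).
#' @param output_scale `"log2"` (default) or `"counts"`; counts are drawn from
#'   a negative binomial whose log-scale dispersion matches `noise_sd`.
#' @param seed Integer RNG seed; identical configs give identical screens.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_genes = 5000,
                              n_orfs = 10,
                              replicates_per_orf = 3,
                              n_batches = 3,
                              controls_per_batch = 3,
                              baseline_log2_mean = 6,
                              baseline_log2_sd = 2,
                              noise_sd = 0.25,
                              batch_sd = 0.3,
                              hits_per_orf = 50,
                              effect_low = 1.5,
                              effect_high = 3,
                              frac_undetectable = 0.1,
                              detection_floor_log2 = 3,
                              libsize_cv = 0.15,
                              output_scale = c("log2", "counts"),
                              seed = 1L) {
  output_scale <- match.arg(output_scale)
  if (n_genes < 1 || n_orfs < 1 || replicates_per_orf < 1 ||
      n_batches < 1 || controls_per_batch < 1)
    stop("dimensions (genes, ORFs, replicates, batches, controls) must be positive",
         call. = FALSE)
  if (noise_sd < 0 || batch_sd < 0 || libsize_cv < 0)
    stop("noise_sd, batch_sd and libsize_cv must be non-negative", call. = FALSE)
  if (hits_per_orf < 0 || hits_per_orf > n_genes)
    stop("`hits_per_orf` must be in [0, n_genes]", call. = FALSE)
  if (effect_low > effect_high)
    stop("`effect_low` must not exceed `effect_high`", call. = FALSE)
  if (effect_low < 1 && hits_per_orf > 0)
    warning("effect_low < 1: planted effects may fall below the 2-fold hit criterion",
            call. = FALSE)
  if (frac_undetectable < 0 || frac_undetectable > 1)
    stop("`frac_undetectable` must be in [0, 1]", call. = FALSE)
  structure(as.list(environment()), class = "simulation_config")
}

#' Simulate a synthetic ORF-overexpression screen
#'
#' Builds a genes x samples expression matrix, its sample sheet, and the
#' planted ground truth. Per-gene baselines are drawn once and shared across
#' samples; a `frac_undetectable` subset of genes is placed below the detection
#' floor; every ORF is assigned to exactly one batch; per-gene batch shifts
#' apply to all samples of a batch (controls included); planted signed effects
#' are added only to that ORF's replicate columns, on genes comfortably above
#' the detection floor (a HIT is by definition detectable); and independent
#' Gaussian noise is added per sample. On the counts scale, log2 means are
#' exponentiated and drawn from a negative binomial with multiplicative
#' library-size factors of the configured CV.
#'
#' @param config A [simulation_config()].
#' @return List with `matrix` (an [expression_matrix]), `samples` (sample
#'   sheet data.frame), and `truth` (data.frame `gene`, `condition`, `effect`
#'   — at most one entry per gene and condition).
#' @export
simulate_screen <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  cfg <- config

  genes <- sprintf("gene%05d", seq_len(cfg$n_genes))
  orfs <- sprintf("ORF%02d", seq_len(cfg$n_orfs))
  orf_batch <- sprintf("B%d", rep_len(seq_len(cfg$n_batches), cfg$n_orfs))
  names(orf_batch) <- orfs

  orf_samples <- data.frame(
    sample = paste0(rep(orfs, each = cfg$replicates_per_orf), "_r",
                    rep(seq_len(cfg$replicates_per_orf), cfg$n_orfs)),
    condition = rep(orfs, each = cfg$replicates_per_orf),
    replicate = rep(seq_len(cfg$replicates_per_orf), cfg$n_orfs),
    batch = rep(orf_batch, each = cfg$replicates_per_orf),
    is_control = FALSE, stringsAsFactors = FALSE)
  ctrl_samples <- data.frame(
    sample = paste0("CTRL_", rep(sprintf("B%d", seq_len(cfg$n_batches)),
                                 each = cfg$controls_per_batch), "_r",
                    rep(seq_len(cfg$controls_per_batch), cfg$n_batches)),
    condition = "CONTROL",
    replicate = rep(seq_len(cfg$controls_per_batch), cfg$n_batches),
    batch = rep(sprintf("B%d", seq_len(cfg$n_batches)), each = cfg$controls_per_batch),
    is_control = TRUE, stringsAsFactors = FALSE)
  sheet <- rbind(orf_samples, ctrl_samples)
  rownames(sheet) <- NULL

  baseline <- stats::rnorm(cfg$n_genes, cfg$baseline_log2_mean, cfg$baseline_log2_sd)
  n_undet <- round(cfg$frac_undetectable * cfg$n_genes)
  if (n_undet > 0) {
    undet <- sample.int(cfg$n_genes, n_undet)
    baseline[undet] <- cfg$detection_floor_log2 - 1 - stats::runif(n_undet)
  }
  names(baseline) <- genes

  batch_ids <- sprintf("B%d", seq_len(cfg$n_batches))
  batch_shift <- matrix(stats::rnorm(cfg$n_genes * cfg$n_batches, 0, cfg$batch_sd),
                        cfg$n_genes, cfg$n_batches,
                        dimnames = list(genes, batch_ids))

  # planted truth: only genes at least 1 log2 unit above the floor are eligible
  eligible <- which(baseline >= cfg$detection_floor_log2 + 1)
  truth <- data.frame(gene = character(), condition = character(),
                      effect = numeric(), stringsAsFactors = FALSE)
  planted <- matrix(0, cfg$n_genes, cfg$n_orfs, dimnames = list(genes, orfs))
  if (cfg$hits_per_orf > 0) {
    if (length(eligible) < cfg$hits_per_orf)
      stop("not enough detectable genes to plant ", cfg$hits_per_orf,
           " hits per ORF", call. = FALSE)
    rows <- vector("list", cfg$n_orfs)
    for (i in seq_len(cfg$n_orfs)) {
      idx <- sample(eligible, cfg$hits_per_orf)
      mag <- stats::runif(cfg$hits_per_orf, cfg$effect_low, cfg$effect_high)
      sgn <- sample(c(-1, 1), cfg$hits_per_orf, replace = TRUE)
      eff <- sgn * mag
      planted[idx, i] <- eff
      rows[[i]] <- data.frame(gene = genes[idx], condition = orfs[i],
                              effect = eff, stringsAsFactors = FALSE)
    }
    truth <- do.call(rbind, rows)
    rownames(truth) <- NULL
  }

  n_samples <- nrow(sheet)
  log2_vals <- matrix(baseline, cfg$n_genes, n_samples,
                      dimnames = list(genes, sheet$sample))
  log2_vals <- log2_vals + batch_shift[, sheet$batch, drop = FALSE]
  is_orf <- !sheet$is_control
  log2_vals[, is_orf] <- log2_vals[, is_orf, drop = FALSE] +
    planted[, sheet$condition[is_orf], drop = FALSE]
  if (cfg$output_scale == "log2") {
    if (cfg$noise_sd > 0)
      log2_vals <- log2_vals +
        matrix(stats::rnorm(cfg$n_genes * n_samples, 0, cfg$noise_sd),
               cfg$n_genes, n_samples)
    em <- expression_matrix(log2_vals, scale = "log2")
  } else {
    # counts mode: sampling noise comes from the negative binomial, whose
    # dispersion is set so the log-scale spread matches noise_sd
    mu <- 2^log2_vals
    if (cfg$libsize_cv > 0) {
      sdlog <- sqrt(log(1 + cfg$libsize_cv^2))
      libfac <- stats::rlnorm(n_samples, meanlog = -sdlog^2 / 2, sdlog = sdlog)
      mu <- sweep(mu, 2, libfac, "*")
    }
    disp <- (log(2) * max(cfg$noise_sd, 0.05))^2  # log-scale variance -> NB dispersion
    counts <- matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / disp),
                     nrow(mu), ncol(mu), dimnames = dimnames(mu))
    em <- expression_matrix(counts + 0, scale = "counts")
  }

  list(matrix = em, samples = sheet, truth = truth)
}

#' Write a simulated screen to TSV files
#'
#' @param sim Output of [simulate_screen()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the three file paths
#'   (`expression.tsv`, `samples.tsv`, `truth.tsv`).
#' @export
write_screen <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(matrix = file.path(dir, "expression.tsv"),
             samples = file.path(dir, "samples.tsv"),
             truth = file.path(dir, "truth.tsv"))
  write_expression_matrix(sim$matrix, paths["matrix"])
  write_sample_sheet(sim$samples, paths["samples"])
  utils::write.table(sim$truth, paths["truth"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths
}

#' Score recovery of planted effects by called hits
#'
#' Compares called (gene, condition, direction) triples of a chosen tier
#' against the planted truth: sensitivity = recovered / planted, precision =
#' recovered / called, F1 their harmonic mean. An empty call set against a
#' non-empty truth reports precision 0 with `precision_defined = FALSE`.
#'
#' @param hits Hit data frame from [call_hits()].
#' @param truth Truth data frame (`gene`, `condition`, `effect`) from
#'   [simulate_screen()].
#' @param tier Which call tiers count as positives (default `"hit"`).
#' @return List with `sensitivity`, `precision`, `f1`, `n_truth`, `n_called`,
#'   `n_recovered`, `precision_defined`, and `per_direction` counts.
#' @export
score_recovery <- function(hits, truth, tier = "hit") {
  h <- hits[hits$tier %in% tier, , drop = FALSE]
  extra <- setdiff(unique(h$condition), unique(truth$condition))
  if (nrow(truth) > 0 && length(extra))
    stop("called condition(s) absent from truth: ", paste(extra, collapse = ", "),
         call. = FALSE)
  key <- function(gene, condition, dir) paste(gene, condition, dir, sep = "\r")
  truth_dir <- ifelse(truth$effect > 0, "up", "down")
  truth_keys <- key(truth$gene, truth$condition, truth_dir)
  called_keys <- key(h$gene, h$condition, h$direction)
  n_truth <- length(truth_keys)
  n_called <- length(called_keys)
  n_rec <- sum(called_keys %in% truth_keys)
  sens <- if (n_truth > 0) n_rec / n_truth else NA_real_
  prec_defined <- n_called > 0
  prec <- if (prec_defined) n_rec / n_called else 0
  f1 <- if (isTRUE(sens + prec > 0)) 2 * sens * prec / (sens + prec) else 0
  list(sensitivity = sens, precision = prec, f1 = f1,
       n_truth = n_truth, n_called = n_called, n_recovered = n_rec,
       precision_defined = prec_defined,
       per_direction = c(up_called = sum(h$direction == "up"),
                         down_called = sum(h$direction == "down"),
                         up_truth = sum(truth_dir == "up"),
                         down_truth = sum(truth_dir == "down")))
}
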