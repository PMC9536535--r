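# Independent brute-force oracles: direct formula evaluation with explicit
# loops, no shared code with the package implementation.

oracle_median <- function(v) {
  v <- sort(v)
  n <- length(v)
  if (n %% 2 == 1) v[(n + 1) / 2] else (v[n / 2] + v[n / 2 + 1]) / 2
}

oracle_mad_scale <- function(v) {
  m <- oracle_median(v)
  dev <- numeric(length(v))
  for (i in seq_along(v)) dev[i] <- abs(v[i] - m)
  1.4826 * oracle_median(dev)
}

oracle_sd <- function(v) {
  m <- sum(v) / length(v)
  ss <- 0
  for (i in seq_along(v)) ss <- ss + (v[i] - m)^2
  sqrt(ss / (length(v) - 1))
}

# Full screen statistic from condition-level profiles, gene by gene.
oracle_screen <- function(profiles_mat, control, config) {
  genes <- rownames(profiles_mat)
  conds <- colnames(profiles_mat)
  n_g <- length(genes)
  baseline <- numeric(n_g)
  base_conds <- if (config$include_control_in_baseline) conds else setdiff(conds, control)
  for (g in seq_len(n_g)) baseline[g] <- oracle_median(profiles_mat[g, base_conds])
  names(baseline) <- genes
  effects <- matrix(NA_real_, n_g, length(conds), dimnames = list(genes, conds))
  for (g in seq_len(n_g)) for (j in seq_along(conds))
    effects[g, j] <- profiles_mat[g, j] - baseline[g]
  detected <- baseline >= config$detection_floor_log2
  raw_scale <- rep(NA_real_, n_g)
  for (g in seq_len(n_g)) if (detected[g])
    raw_scale[g] <- if (config$variance_estimator == "mad")
      oracle_mad_scale(effects[g, ]) else oracle_sd(effects[g, ])
  floor_val <- config$variance_floor
  if (is.null(floor_val)) floor_val <- 0.25 * oracle_median(raw_scale[detected])
  scale <- raw_scale
  for (g in seq_len(n_g)) if (detected[g] && scale[g] < floor_val) scale[g] <- floor_val
  names(scale) <- genes
  z <- matrix(NA_real_, n_g, length(conds), dimnames = list(genes, conds))
  cls <- matrix("below_detection", n_g, length(conds), dimnames = list(genes, conds))
  for (g in seq_len(n_g)) {
    if (!detected[g]) next
    for (j in seq_along(conds)) {
      z[g, j] <- effects[g, j] / scale[g]
      az <- abs(z[g, j])
      cls[g, j] <- if (az <= config$z_suggestive) "within"
                   else if (az <= config$z_hit) "suggestive" else "outside"
    }
  }
  log2_thr <- log2(config$fold_threshold)
  hit_rows <- list()
  for (j in seq_along(conds)) {
    if (conds[j] == control) next
    for (g in seq_len(n_g)) {
      if (!detected[g]) next
      if (abs(effects[g, j]) <= log2_thr) next
      if (!(cls[g, j] %in% c("outside", "suggestive"))) next
      hit_rows[[length(hit_rows) + 1]] <- data.frame(
        condition = conds[j], gene = genes[g],
        direction = if (effects[g, j] > 0) "up" else "down",
        tier = if (cls[g, j] == "outside") "hit" else "suggestive",
        stringsAsFactors = FALSE)
    }
  }
  hits <- if (length(hit_rows)) do.call(rbind, hit_rows) else
    data.frame(condition = character(), gene = character(),
               direction = character(), tier = character(), stringsAsFactors = FALSE)
  list(baseline = baseline, effects = effects, scale = scale, z = z,
       detected = detected, class = cls, hits = hits)
}

# Exact hypergeometric upper tail by combinatorial summation.
oracle_hyper_tail <- function(k, size_a, size_b, universe) {
  total <- choose(universe, size_b)
  p <- 0
  for (i in k:min(size_a, size_b))
    p <- p + choose(size_a, i) * choose(universe - size_a, size_b - i) / total
  min(p, 1)
}

# Benjamini-Hochberg step-up, spelled out.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) if (m > 1) q_sorted[i] <- min(q_sorted[i], q_sorted[i + 1])
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# Quadratic all-pairs interval overlap, half-open semantics.
oracle_interval_overlaps <- function(a, b) {
  rows <- list()
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    if (a$chrom[i] == b$chrom[j] &&
        max(a$start[i], b$start[j]) < min(a$end[i], b$end[j]))
      rows[[length(rows) + 1]] <- c(i, j)
  }
  if (!length(rows)) return(data.frame(index_a = integer(), index_b = integer()))
  m <- do.call(rbind, rows)
  data.frame(index_a = m[, 1], index_b = m[, 2])
}
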