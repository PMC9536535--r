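#' Screen configuration
#'
#' Thresholds and estimator choices for hit calling.
#'
#' @param fold_threshold Minimum fold effect (on the original scale) a HIT must
#'   exceed; must be > 1. Default 2, i.e. |log2 effect| > 1.
#' @param z_hit |Z| above which a gene is outside the expected range of
#'   variation (hit tier). Default 4.
#' @param z_suggestive |Z| above which a gene is suggestively outside the
#'   range. Default 2; must be < `z_hit`.
#' @param detection_floor_log2 Minimum baseline log2 expression for a gene to
#'   count as detectable. Default 3.
#' @param variance_estimator Per-gene scale estimator for the expected range of
#'   variation: `"mad"` (median absolute deviation x 1.4826, robust to the very
#'   hits being detected; default) or `"sd"`.
#' @param variance_floor Lower bound applied to every per-gene scale. `NULL`
#'   (default) sets it at run time to 0.25 x the median scale over detected
#'   genes, preventing near-constant genes from yielding unbounded Z.
#' @param include_control_in_baseline Whether the pooled control profile
#'   contributes one condition to the baseline median and the variation
#'   estimate. Default TRUE.
#' @return A list of class `screen_config`.
#' @export
screen_config <- function(fold_threshold = 2,
                          z_hit = 4,
                          z_suggestive = 2,
                          detection_floor_log2 = 3,
                          variance_estimator = c("mad", "sd"),
                          variance_floor = NULL,
                          include_control_in_baseline = TRUE) {
  variance_estimator <- match.arg(variance_estimator)
  if (!is.numeric(fold_threshold) || fold_threshold <= 1)
    stop("`fold_threshold` must be > 1", call. = FALSE)
  if (!is.numeric(z_hit) || z_hit <= 0) stop("`z_hit` must be positive", call. = FALSE)
  if (!is.numeric(z_suggestive) || z_suggestive <= 0 || z_suggestive >= z_hit)
    stop("`z_suggestive` must be positive and smaller than `z_hit`", call. = FALSE)
  if (!is.null(variance_floor) && (!is.numeric(variance_floor) || variance_floor < 0))
    stop("`variance_floor` must be NULL or a non-negative number", call. = FALSE)
  structure(list(fold_threshold = fold_threshold,
                 z_hit = z_hit,
                 z_suggestive = z_suggestive,
                 detection_floor_log2 = detection_floor_log2,
                 variance_estimator = variance_estimator,
                 variance_floor = variance_floor,
                 include_control_in_baseline = include_control_in_baseline),
            class = "screen_config")
}

#' Per-gene baseline expression
#'
#' The baseline is the median of a gene's log2 expression across all
#' condition-level profiles (the pooled control counting as one condition).
#' Even numbers of conditions use the mean of the middle two values.
#'
#' @param profiles A `condition_profiles` object from [merge_replicates()].
#' @param config A [screen_config()]; controls whether the control profile is
#'   included.
#' @return Named numeric vector of per-gene baselines.
#' @export
compute_baseline <- function(profiles, config = screen_config()) {
  stopifnot(inherits(profiles, "condition_profiles"))
  vals <- profiles$values
  if (!config$include_control_in_baseline)
    vals <- vals[, colnames(vals) != profiles$control, drop = FALSE]
  if (ncol(vals) < 2)
    stop("need at least two condition profiles to define a baseline", call. = FALSE)
  apply(vals, 1, stats::median)
}

#' Per-condition log2 effects against the baseline
#'
#' The effect of condition c on gene g is `x = profile(g, c) - baseline(g)`:
#' the log2 fold-induction relative to the transcriptome-wide baseline, so
#' effects are additive on the log2 scale and `2^x` is the fold change.
#'
#' @param profiles A `condition_profiles` object.
#' @param baseline Named per-gene baseline from [compute_baseline()]; must
#'   cover the same gene universe.
#' @return Genes x conditions matrix of effects.
#' @export
compute_effects <- function(profiles, baseline) {
  stopifnot(inherits(profiles, "condition_profiles"))
  if (!identical(sort(names(baseline)), sort(rownames(profiles$values))))
    stop("baseline gene universe does not match the profiles", call. = FALSE)
  profiles$values - baseline[rownames(profiles$values)]
}

#' Convert a log2 effect to a fold change
#'
#' An effect of `x` on the log2 scale corresponds to a multiplicative fold
#' change `FC = 2^x`: an effect of 1 is a doubling (FC = 2), an effect of -1
#' a halving.
#'
#' @param x Numeric vector of log2 effects.
#' @return `2^x`.
#' @export
effect_to_fc <- function(x) 2^x

#' Estimate the expected range of variation per gene
#'
#' The scale `s_g` of each detected gene is estimated from its effects across
#' all conditions — by default the median absolute deviation scaled by 1.4826
#' (a robust standard-deviation estimate insensitive to the few conditions with
#' genuine effects), optionally the plain standard deviation. Scales are then
#' floored (see [screen_config()]) so that near-constant genes cannot produce
#' unbounded Z-scores. Undetected genes get `NA`.
#'
#' @param effects Genes x conditions effects matrix.
#' @param detected Logical per-gene detectability vector (same order as rows).
#' @param config A [screen_config()].
#' @return Named numeric vector of per-gene scales (NA where undetected).
#' @export
estimate_expected_variation <- function(effects, detected, config = screen_config()) {
  if (ncol(effects) < 3)
    stop("need at least 3 conditions to estimate the expected range of variation",
         call. = FALSE)
  if (length(detected) != nrow(effects))
    stop("`detected` must have one entry per gene", call. = FALSE)
  s <- rep(NA_real_, nrow(effects))
  names(s) <- rownames(effects)
  floor_val <- config$variance_floor
  if (any(detected)) {
    est <- switch(config$variance_estimator,
                  mad = function(v) stats::mad(v, constant = 1.4826),
                  sd  = stats::sd)
    raw <- apply(effects[detected, , drop = FALSE], 1, est)
    if (is.null(floor_val)) floor_val <- 0.25 * stats::median(raw)
    s[detected] <- pmax(raw, floor_val)
  }
  attr(s, "variance_floor") <- floor_val
  s
}

#' Classify effects against the expected range of variation
#'
#' Four-way classification per (gene, condition): `below_detection` when the
#' gene's baseline falls under the detection floor; otherwise `within` when
#' |Z| <= z_suggestive, `suggestive` when z_suggestive < |Z| <= z_hit, and
#' `outside` when |Z| > z_hit.
#'
#' @param z Genes x conditions matrix of Z-scores (NA rows for undetected).
#' @param detected Logical per-gene detectability vector.
#' @param config A [screen_config()].
#' @return Character matrix of class labels with the same dimensions as `z`.
#' @export
classify_effects <- function(z, detected, config = screen_config()) {
  cls <- matrix("below_detection", nrow(z), ncol(z), dimnames = dimnames(z))
  if (any(detected)) {
    az <- abs(z[detected, , drop = FALSE])
    lab <- ifelse(az <= config$z_suggestive, "within",
                  ifelse(az <= config$z_hit, "suggestive", "outside"))
    cls[detected, ] <- lab
  }
  cls
}

#' Compute the full effect table for a screen
#'
#' Runs the whole statistic over merged condition profiles: per-gene baseline
#' (median log2 expression across conditions), per-condition log2 effects,
#' detectability against the floor, robust per-gene expected-variation scales,
#' Z-scores, and the four-way classification.
#'
#' @param profiles A `condition_profiles` object from [merge_replicates()].
#' @param config A [screen_config()].
#' @return An object of class `effect_table`: list with `baseline`, `effects`,
#'   `scale`, `z`, `detected`, `class`, `conditions`, `control`, `config`.
#' @export
screen_effects <- function(profiles, config = screen_config()) {
  stopifnot(inherits(profiles, "condition_profiles"))
  baseline <- compute_baseline(profiles, config)
  effects <- compute_effects(profiles, baseline)
  detected <- baseline >= config$detection_floor_log2
  s <- estimate_expected_variation(effects, detected, config)
  z <- effects / s
  z[!detected, ] <- NA_real_
  cls <- classify_effects(z, detected, config)
  structure(list(baseline = baseline,
                 effects = effects,
                 scale = s,
                 z = z,
                 detected = detected,
                 class = cls,
                 conditions = colnames(effects),
                 control = profiles$control,
                 config = config),
            class = "effect_table")
}

#' @export
print.effect_table <- function(x, ...) {
  cat(sprintf("<effect_table> %d genes (%d detected) x %d conditions\n",
              length(x$baseline), sum(x$detected), length(x$conditions)))
  invisible(x)
}

#' Call HITS per condition
#'
#' A HIT is a detectable gene whose fold effect computed from the combined
#' replicates exceeds the fold threshold AND whose expression lies outside the
#' expected range of variation (|Z| > z_hit). Genes passing the fold threshold
#' with z_suggestive < |Z| <= z_hit form the `suggestive` tier. Direction is
#' the sign of the effect. The control condition yields no calls.
#'
#' @param et An `effect_table` from [screen_effects()].
#' @return Data frame with columns `condition`, `gene`, `direction`
#'   (`up`/`down`), `tier` (`hit`/`suggestive`), `effect`, `z`.
#' @export
call_hits <- function(et) {
  stopifnot(inherits(et, "effect_table"))
  cfg <- et$config
  log2_thr <- log2(cfg$fold_threshold)
  conds <- setdiff(et$conditions, et$control)
  out <- vector("list", length(conds))
  for (i in seq_along(conds)) {
    cond <- conds[i]
    x <- et$effects[, cond]
    cls <- et$class[, cond]
    keep <- et$detected & abs(x) > log2_thr & cls %in% c("outside", "suggestive")
    if (!any(keep)) next
    out[[i]] <- data.frame(
      condition = cond,
      gene = names(x)[keep],
      direction = ifelse(x[keep] > 0, "up", "down"),
      tier = ifelse(cls[keep] == "outside", "hit", "suggestive"),
      effect = unname(x[keep]),
      z = unname(et$z[keep, cond]),
      stringsAsFactors = FALSE, row.names = NULL)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(condition = character(), gene = character(),
                      direction = character(), tier = character(),
                      effect = numeric(), z = numeric(), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Tabulate HIT counts per condition
#'
#' Counts hit-tier calls (up, down, total) per condition, ordered by
#' decreasing total with alphabetical tie-break — the ordering used to rank
#' ORFs by their impact on the transcriptome.
#'
#' @param hits Hit data frame from [call_hits()].
#' @param conditions Optional character vector of all screened conditions so
#'   that conditions with zero hits appear with zero counts.
#' @return Data frame with columns `condition`, `n_up`, `n_down`, `n_total`.
#' @export
count_hits <- function(hits, conditions = NULL) {
  h <- hits[hits$tier == "hit", , drop = FALSE]
  conds <- conditions
  if (is.null(conds)) conds <- sort(unique(h$condition))
  n_up <- vapply(conds, function(cc) sum(h$condition == cc & h$direction == "up"), 0L)
  n_down <- vapply(conds, function(cc) sum(h$condition == cc & h$direction == "down"), 0L)
  res <- data.frame(condition = conds, n_up = n_up, n_down = n_down,
                    n_total = n_up + n_down, stringsAsFactors = FALSE, row.names = NULL)
  res[order(-res$n_total, res$condition), , drop = FALSE]
}

#' Long-format MA-plot table
#'
#' One row per (gene, condition) with the baseline (x-axis of an MA view), the
#' log2 effect (y-axis), the Z-score, and the class label — the data behind
#' per-ORF MA plots.
#'
#' @param et An `effect_table`.
#' @param conditions Conditions to include (default: all non-control).
#' @return Data frame with columns `gene`, `condition`, `baseline`, `effect`,
#'   `z`, `detected`, `class`.
#' @export
ma_table <- function(et, conditions = NULL) {
  stopifnot(inherits(et, "effect_table"))
  if (is.null(conditions)) conditions <- setdiff(et$conditions, et$control)
  bad <- setdiff(conditions, et$conditions)
  if (length(bad)) stop("unknown condition(s): ", paste(bad, collapse = ", "), call. = FALSE)
  genes <- names(et$baseline)
  do.call(rbind, lapply(conditions, function(cond) {
    data.frame(gene = genes,
               condition = cond,
               baseline = unname(et$baseline),
               effect = unname(et$effects[, cond]),
               z = unname(et$z[, cond]),
               detected = unname(et$detected),
               class = unname(et$class[, cond]),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
}

#' MA plot for one condition
#'
#' Baseline log2 expression against log2 effect, coloured by classification.
#' Requires ggplot2.
#'
#' @param et An `effect_table`.
#' @param condition Condition to plot.
#' @return A ggplot object.
#' @export
plot_ma <- function(et, condition) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plot_ma()", call. = FALSE)
  tab <- ma_table(et, condition)
  tab$class <- factor(tab$class,
                      levels = c("below_detection", "within", "suggestive", "outside"))
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$baseline, y = .data$effect,
                                    colour = .data$class)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(below_detection = "grey70",
                                            within = "skyblue3",
                                            suggestive = "orange",
                                            outside = "red3"),
                                 drop = FALSE) +
    ggplot2::labs(x = "baseline (log2 median expression)",
                  y = sprintf("log2 effect (%s)", condition),
                  colour = NULL) +
    ggplot2::theme_minimal()
}
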