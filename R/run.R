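#' Run the screen pipeline on in-memory objects
#'
#' Normalization (counts input only), batch anchoring on controls, replicate
#' merging, effect-table computation and hit calling, without file I/O.
#'
#' @param em An [expression_matrix].
#' @param sheet A sample sheet data.frame.
#' @param config A [screen_config()].
#' @param pseudocount Pseudocount for counts normalization.
#' @param anchor Whether to anchor batches on controls (default TRUE).
#' @return List with `effect_table`, `hits`, `counts`, `profiles`.
#' @export
screen_pipeline <- function(em, sheet, config = screen_config(),
                            pseudocount = 1, anchor = TRUE) {
  validate_screen_inputs(em, sheet)
  em <- normalize_log2(em, pseudocount)
  if (anchor) em <- anchor_batches(em, sheet)
  profiles <- merge_replicates(em, sheet)
  et <- screen_effects(profiles, config)
  hits <- call_hits(et)
  counts <- count_hits(hits, conditions = setdiff(et$conditions, et$control))
  list(effect_table = et, hits = hits, counts = counts, profiles = profiles)
}

#' Run the full screen pipeline on files
#'
#' Reads an expression matrix and sample sheet, validates them, normalizes to
#' log2 (counts input only), anchors batches on the empty-vector controls,
#' merges replicates, computes the effect table, calls HITS, and writes every
#' stage output plus a run manifest to `out_dir`:
#' `effect_table.tsv`, `hits.tsv`, `hit_counts.tsv`, `ma_table.tsv`,
#' `manifest.txt`. The pipeline itself is deterministic; rerunning on identical
#' inputs reproduces identical output digests.
#'
#' @param matrix_path Path to the expression matrix TSV.
#' @param samples_path Path to the sample sheet TSV.
#' @param out_dir Output directory (created if needed).
#' @param config A [screen_config()].
#' @param scale Scale of the stored matrix (`"log2"` or `"counts"`).
#' @param pseudocount Pseudocount for counts normalization.
#' @param anchor Whether to anchor batches on controls (default TRUE).
#' @param seed Optional seed recorded in the manifest (the pipeline uses no
#'   randomness; the seed documents the upstream data generation).
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the `effect_table`, `hits`, `counts`,
#'   `paths`, and the manifest lines.
#' @export
run_screen <- function(matrix_path, samples_path, out_dir,
                       config = screen_config(),
                       scale = c("log2", "counts"),
                       pseudocount = 1,
                       anchor = TRUE,
                       seed = NA_integer_,
                       quiet = FALSE) {
  scale <- match.arg(scale)
  say <- function(...) if (!quiet) message(...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
  }

  em <- stage("read_matrix", read_expression_matrix(matrix_path, scale))
  sheet <- stage("read_samples", read_sample_sheet(samples_path))
  stage("validate", validate_screen_inputs(em, sheet))
  say(sprintf("read %d genes x %d samples (%d conditions, %d batches)",
              nrow(em$values), ncol(em$values),
              length(unique(sheet$condition)), length(unique(sheet$batch))))

  emn <- stage("normalize", normalize_log2(em, pseudocount))
  if (anchor) emn <- stage("anchor", anchor_batches(emn, sheet))
  profiles <- stage("merge", merge_replicates(emn, sheet))
  et <- stage("effects", screen_effects(profiles, config))
  hits <- stage("call_hits", call_hits(et))
  counts <- stage("count_hits",
                  count_hits(hits, conditions = setdiff(et$conditions, et$control)))
  ma <- stage("ma_table", ma_table(et))
  say(sprintf("thresholds: fold > %g, |Z| > %g (hit), |Z| > %g (suggestive), floor %g",
              config$fold_threshold, config$z_hit, config$z_suggestive,
              config$detection_floor_log2))
  say(sprintf("%d detected genes; %d hit-tier and %d suggestive-tier calls",
              sum(et$detected), sum(hits$tier == "hit"),
              sum(hits$tier == "suggestive")))

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(effect_table = file.path(out_dir, "effect_table.tsv"),
             hits = file.path(out_dir, "hits.tsv"),
             hit_counts = file.path(out_dir, "hit_counts.tsv"),
             ma_table = file.path(out_dir, "ma_table.tsv"))
  wt <- function(df, p) utils::write.table(df, p, sep = "\t", quote = FALSE,
                                           row.names = FALSE)
  et_long <- ma_table(et, conditions = et$conditions)
  et_long$scale <- et$scale[et_long$gene]
  wt(et_long, paths["effect_table"])
  wt(hits, paths["hits"])
  wt(counts, paths["hit_counts"])
  wt(ma, paths["ma_table"])

  manifest <- c(
    sprintf("tool_version: orfscreen %s",
            as.character(utils::packageVersion("orfscreen"))),
    sprintf("timestamp: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    sprintf("seed: %s", seed),
    sprintf("input_matrix: %s md5=%s", matrix_path, unname(tools::md5sum(matrix_path))),
    sprintf("input_samples: %s md5=%s", samples_path, unname(tools::md5sum(samples_path))),
    sprintf("config_fold_threshold: %g", config$fold_threshold),
    sprintf("config_z_hit: %g", config$z_hit),
    sprintf("config_z_suggestive: %g", config$z_suggestive),
    sprintf("config_detection_floor_log2: %g", config$detection_floor_log2),
    sprintf("config_variance_estimator: %s", config$variance_estimator),
    sprintf("config_variance_floor: %s",
            if (is.null(config$variance_floor)) "auto(0.25*median)" else config$variance_floor),
    sprintf("config_anchor_batches: %s", anchor),
    sprintf("config_pseudocount: %g", pseudocount),
    sprintf("n_genes: %d", nrow(em$values)),
    sprintf("n_samples: %d", ncol(em$values)),
    sprintf("n_conditions: %d", length(et$conditions)),
    sprintf("n_detected_genes: %d", sum(et$detected)),
    sprintf("n_hits: %d", sum(hits$tier == "hit")),
    sprintf("n_suggestive: %d", sum(hits$tier == "suggestive")),
    vapply(names(paths), function(k)
      sprintf("output_%s: %s rows=%d md5=%s", k, paths[[k]],
              length(readLines(paths[[k]])) - 1L,
              unname(tools::md5sum(paths[[k]]))), ""))
  manifest_path <- file.path(out_dir, "manifest.txt")
  writeLines(manifest, manifest_path)
  paths <- c(paths, manifest = manifest_path)

  invisible(list(effect_table = et, hits = hits, counts = counts,
                 paths = paths, manifest = manifest))
}
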