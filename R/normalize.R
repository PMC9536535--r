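#' Normalize an expression matrix to the log2 scale
#'
#' Counts-scale input is library-size normalized to counts-per-million and then
#' log2-transformed with a pseudocount: `log2(cpm + pseudocount)`. Input already
#' on the log2 scale passes through unchanged, so the function is safe to call
#' unconditionally at the head of the pipeline.
#'
#' @param em An [expression_matrix].
#' @param pseudocount Positive value added before the log2 transform
#'   (default 1).
#' @return A log2-scale [expression_matrix].
#' @export
normalize_log2 <- function(em, pseudocount = 1) {
  stopifnot(inherits(em, "expression_matrix"))
  if (em$scale == "log2") return(em)
  if (!is.numeric(pseudocount) || length(pseudocount) != 1 || pseudocount <= 0)
    stop("`pseudocount` must be a single positive number", call. = FALSE)
  libsize <- colSums(em$values)
  zero <- colnames(em$values)[libsize == 0]
  if (length(zero))
    stop("all-zero column(s): ", paste(zero, collapse = ", "), call. = FALSE)
  cpm <- sweep(em$values, 2, libsize / 1e6, "/")
  expression_matrix(log2(cpm + pseudocount), scale = "log2")
}

#' Anchor batches on their control samples
#'
#' Each experimental batch carries its own empty-vector control samples. For
#' every gene, the batch mean of those controls is shifted to the global
#' control mean: sample values in batch b are reduced by
#' `mean(controls in b) - mean(all controls)`. Within-batch differences between
#' samples are untouched, and after anchoring the per-gene control means of all
#' batches coincide, so condition profiles from different batches are
#' comparable. The operation is idempotent.
#'
#' @param em A log2-scale [expression_matrix].
#' @param sheet A sample sheet data.frame; every batch must contain at least
#'   one control sample.
#' @return The anchored [expression_matrix].
#' @export
anchor_batches <- function(em, sheet) {
  stopifnot(inherits(em, "expression_matrix"))
  if (em$scale != "log2")
    stop("anchor_batches() expects a log2-scale matrix; run normalize_log2() first",
         call. = FALSE)
  sheet <- sheet[match(colnames(em$values), sheet$sample), , drop = FALSE]
  if (anyNA(sheet$sample))
    stop("sample sheet does not cover all matrix columns", call. = FALSE)
  ctrl <- sheet$is_control
  if (!any(ctrl)) stop("no control samples in sheet", call. = FALSE)
  batches <- unique(sheet$batch)
  missing_ctrl <- batches[!batches %in% sheet$batch[ctrl]]
  if (length(missing_ctrl))
    stop("batch(es) without controls: ", paste(missing_ctrl, collapse = ", "), call. = FALSE)
  global_ctrl_mean <- rowMeans(em$values[, ctrl, drop = FALSE])
  out <- em$values
  for (b in batches) {
    in_b <- sheet$batch == b
    shift <- rowMeans(em$values[, in_b & ctrl, drop = FALSE]) - global_ctrl_mean
    out[, in_b] <- out[, in_b, drop = FALSE] - shift
  }
  expression_matrix(out, scale = "log2")
}

#' Merge replicate samples into condition-level profiles
#'
#' For every condition (each ORF, plus the single control condition pooled over
#' all batches), the per-gene profile is the unweighted arithmetic mean of its
#' replicate columns on the log2 scale — i.e. the geometric mean on the
#' original scale, so the fold effect downstream is the one computed from the
#' combined replicates.
#'
#' @param em An anchored log2-scale [expression_matrix].
#' @param sheet A sample sheet data.frame.
#' @return An object of class `condition_profiles`: list with `values`
#'   (genes x conditions matrix), `n_replicates` (named integer vector) and
#'   `control` (the control condition label).
#' @export
merge_replicates <- function(em, sheet) {
  stopifnot(inherits(em, "expression_matrix"))
  if (em$scale != "log2")
    stop("merge_replicates() expects a log2-scale matrix", call. = FALSE)
  sheet <- sheet[match(colnames(em$values), sheet$sample), , drop = FALSE]
  if (anyNA(sheet$sample))
    stop("sample sheet does not cover all matrix columns", call. = FALSE)
  conditions <- unique(sheet$condition)
  n_rep <- integer(length(conditions))
  names(n_rep) <- conditions
  prof <- matrix(NA_real_, nrow(em$values), length(conditions),
                 dimnames = list(rownames(em$values), conditions))
  for (cond in conditions) {
    cols <- sheet$condition == cond
    if (!any(cols)) stop("condition with zero samples: ", cond, call. = FALSE)
    n_rep[cond] <- sum(cols)
    prof[, cond] <- rowMeans(em$values[, cols, drop = FALSE])
  }
  structure(list(values = prof, n_replicates = n_rep,
                 control = control_label(sheet)),
            class = "condition_profiles")
}

#' @export
print.condition_profiles <- function(x, ...) {
  cat(sprintf("<condition_profiles> %d genes x %d conditions (control: %s)\n",
              nrow(x$values), ncol(x$values), x$control))
  invisible(x)
}
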