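#' Construct an expression matrix
#'
#' A genes x samples matrix of expression values tagged with its scale:
#' `"counts"` (non-negative raw abundances) or `"log2"` (log2-transformed,
#' library-size-normalized values ready for effect computation).
#'
#' @param values Numeric matrix with unique, non-empty rownames (gene ids) and
#'   colnames (sample ids). All values must be finite.
#' @param scale One of `"counts"` or `"log2"`.
#' @return An object of class `expression_matrix`: a list with elements
#'   `values` (the matrix) and `scale`.
#' @export
expression_matrix <- function(values, scale = c("log2", "counts")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have rownames (genes) and colnames (samples)", call. = FALSE)
  dup_g <- unique(rownames(values)[duplicated(rownames(values))])
  if (length(dup_g))
    stop("duplicate gene id(s): ", paste(dup_g, collapse = ", "), call. = FALSE)
  dup_s <- unique(colnames(values)[duplicated(colnames(values))])
  if (length(dup_s))
    stop("duplicate sample id(s): ", paste(dup_s, collapse = ", "), call. = FALSE)
  if (any(!is.finite(values)))
    stop("expression values must be finite", call. = FALSE)
  if (scale == "counts" && any(values < 0))
    stop("counts-scale values must be non-negative", call. = FALSE)
  structure(list(values = values, scale = scale), class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d genes x %d samples, scale = %s\n",
              nrow(x$values), ncol(x$values), x$scale))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Read an expression matrix from TSV
#'
#' Expects a header row of sample ids and a first column of gene ids.
#'
#' @param path Path to a tab-separated file.
#' @param scale Scale tag of the stored values (`"log2"` or `"counts"`).
#' @return An [expression_matrix].
#' @export
read_expression_matrix <- function(path, scale = c("log2", "counts")) {
  scale <- match.arg(scale)
  if (!file.exists(path)) stop("expression matrix file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          colClasses = NA, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("expression matrix needs a gene column plus >=1 sample column", call. = FALSE)
  genes <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- genes
  expression_matrix(m, scale)
}

#' Write an expression matrix to TSV
#'
#' @param em An [expression_matrix].
#' @param path Output path; first column `gene`, then one column per sample.
#' @export
write_expression_matrix <- function(em, path) {
  stopifnot(inherits(em, "expression_matrix"))
  df <- data.frame(gene = rownames(em$values), em$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample sheet from TSV
#'
#' Columns: `sample`, `condition` (ORF label, or the shared control label for
#' empty-vector samples), `replicate`, `batch`, `is_control` (logical).
#'
#' @param path Path to a tab-separated file with the columns above.
#' @return A data.frame sample sheet.
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) stop("sample sheet file not found: ", path, call. = FALSE)
  sheet <- utils::read.delim(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
  needed <- c("sample", "condition", "replicate", "batch", "is_control")
  missing <- setdiff(needed, names(sheet))
  if (length(missing))
    stop("sample sheet lacks column(s): ", paste(missing, collapse = ", "), call. = FALSE)
  sheet$sample <- as.character(sheet$sample)
  sheet$condition <- as.character(sheet$condition)
  sheet$batch <- as.character(sheet$batch)
  sheet$is_control <- as.logical(sheet$is_control)
  if (anyNA(sheet$is_control)) stop("is_control must be TRUE/FALSE", call. = FALSE)
  sheet
}

#' Write a sample sheet to TSV
#' @param sheet A sample sheet data.frame.
#' @param path Output path.
#' @export
write_sample_sheet <- function(sheet, path) {
  utils::write.table(sheet, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Validate an expression matrix against its sample sheet
#'
#' Checks that sample ids match one-to-one, that every batch contains at least
#' one control sample, that control samples share a single condition label, and
#' that every non-control condition maps to exactly one batch.
#'
#' @param em An [expression_matrix].
#' @param sheet A sample sheet data.frame.
#' @return Invisibly `TRUE`; errors describe every violation found.
#' @export
validate_screen_inputs <- function(em, sheet) {
  stopifnot(inherits(em, "expression_matrix"))
  problems <- character()
  dup <- unique(sheet$sample[duplicated(sheet$sample)])
  if (length(dup))
    problems <- c(problems, paste0("duplicate sample id(s) in sheet: ", paste(dup, collapse = ", ")))
  only_m <- setdiff(colnames(em$values), sheet$sample)
  only_s <- setdiff(sheet$sample, colnames(em$values))
  if (length(only_m))
    problems <- c(problems, paste0("samples in matrix but not sheet: ", paste(only_m, collapse = ", ")))
  if (length(only_s))
    problems <- c(problems, paste0("samples in sheet but not matrix: ", paste(only_s, collapse = ", ")))
  ctrl_by_batch <- tapply(sheet$is_control, sheet$batch, any)
  no_ctrl <- names(ctrl_by_batch)[!ctrl_by_batch]
  if (length(no_ctrl))
    problems <- c(problems, paste0("batch(es) without a control sample: ", paste(no_ctrl, collapse = ", ")))
  ctrl_labels <- unique(sheet$condition[sheet$is_control])
  if (length(ctrl_labels) > 1)
    problems <- c(problems, paste0("control samples carry multiple condition labels: ",
                                   paste(ctrl_labels, collapse = ", ")))
  if (length(ctrl_labels) == 0)
    problems <- c(problems, "sample sheet contains no control samples")
  noncontrol <- sheet[!sheet$is_control, , drop = FALSE]
  if (nrow(noncontrol)) {
    nb <- tapply(noncontrol$batch, noncontrol$condition, function(b) length(unique(b)))
    multi <- names(nb)[nb > 1]
    if (length(multi))
      problems <- c(problems, paste0("condition(s) spanning multiple batches: ",
                                     paste(multi, collapse = ", ")))
  }
  if (length(problems))
    stop("invalid screen inputs:\n  - ", paste(problems, collapse = "\n  - "), call. = FALSE)
  invisible(TRUE)
}

#' Control condition label of a sample sheet
#' @param sheet A sample sheet data.frame.
#' @return The single condition label shared by all control samples.
#' @export
control_label <- function(sheet) {
  lab <- unique(sheet$condition[sheet$is_control])
  if (length(lab) != 1)
    stop("expected exactly one control condition label, found: ",
         paste(lab, collapse = ", "), call. = FALSE)
  lab
}
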