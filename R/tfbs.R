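#' Construct an interval set
#'
#' Genomic intervals in the BED convention: 0-based, half-open `[start, end)`.
#' Strand is ignored; promoter windows are expected to be pre-computed by the
#' caller.
#'
#' @param chrom Character vector of chromosome names.
#' @param start,end Integer-valued coordinates with `start < end`, 0-based
#'   half-open.
#' @param name Record names (e.g. promoter gene or TF name); defaults to
#'   `region1..n`.
#' @return A data.frame of class `interval_set` with columns `chrom`, `start`,
#'   `end`, `name`.
#' @export
interval_set <- function(chrom, start, end, name = NULL) {
  if (is.null(name)) name <- sprintf("region%d", seq_along(chrom))
  if (length(chrom) != length(start) || length(start) != length(end) ||
      length(end) != length(name))
    stop("chrom, start, end, name must have equal length", call. = FALSE)
  if (anyNA(chrom) || anyNA(start) || anyNA(end))
    stop("interval coordinates must not contain NA", call. = FALSE)
  if (!is.numeric(start) || !is.numeric(end) ||
      any(start != floor(start)) || any(end != floor(end)))
    stop("start and end must be integer-valued", call. = FALSE)
  if (any(start >= end))
    stop("every interval must satisfy start < end (0-based half-open)", call. = FALSE)
  structure(data.frame(chrom = as.character(chrom), start = as.integer(start),
                       end = as.integer(end), name = as.character(name),
                       stringsAsFactors = FALSE),
            class = c("interval_set", "data.frame"))
}

# BED half-open [start, end) -> 1-based closed IRanges [start+1, end];
# seqlevels can be widened so two sets always live in a shared universe
as_granges <- function(iv, seqlevels = unique(iv$chrom)) {
  GenomicRanges::GRanges(seqnames = factor(iv$chrom, levels = seqlevels),
                         ranges = IRanges::IRanges(start = iv$start + 1L,
                                                   end = iv$end),
                         name = iv$name)
}

#' Read a BED file as an interval set
#'
#' Minimum columns chrom/start/end; column 4, when present, becomes the record
#' name. Coordinates are kept in the BED 0-based half-open convention.
#'
#' @param path Path to a BED file.
#' @return An [interval_set()].
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path, call. = FALSE)
  gr <- tryCatch(rtracklayer::import(path, format = "BED"),
                 error = function(e) stop("malformed BED file ", path, ": ",
                                          conditionMessage(e), call. = FALSE))
  nm <- gr$name
  if (is.null(nm) || all(is.na(nm))) nm <- sprintf("region%d", seq_along(gr))
  interval_set(chrom = as.character(GenomicRanges::seqnames(gr)),
               start = GenomicRanges::start(gr) - 1L,
               end = GenomicRanges::end(gr),
               name = nm)
}

#' Write an interval set as BED
#' @param iv An [interval_set()].
#' @param path Output path.
#' @export
write_bed <- function(iv, path) {
  stopifnot(inherits(iv, "interval_set"))
  rtracklayer::export(as_granges(iv), path, format = "BED")
  invisible(path)
}

#' Intersect two interval sets
#'
#' Reports every pair (i, j) with `a[i]` and `b[j]` on the same chromosome and
#' `max(start) < min(end)` under half-open semantics: abutting intervals do not
#' overlap.
#'
#' @param a,b [interval_set()] objects.
#' @return Data frame of overlapping pairs: indices and names from both sets.
#' @export
intersect_intervals <- function(a, b) {
  stopifnot(inherits(a, "interval_set"), inherits(b, "interval_set"))
  lv <- union(a$chrom, b$chrom)
  hits <- GenomicRanges::findOverlaps(as_granges(a, lv), as_granges(b, lv))
  qi <- S4Vectors::queryHits(hits)
  sj <- S4Vectors::subjectHits(hits)
  data.frame(index_a = qi, index_b = sj,
             name_a = a$name[qi], name_b = b$name[sj],
             stringsAsFactors = FALSE)
}

#' Factors whose peaks overlap every promoter in a query set
#'
#' Generic form of the shared-promoter-binding question: given promoter windows
#' and binding intervals grouped by factor name, return the factors with at
#' least one peak overlapping each promoter. Adding peaks can only add factors.
#'
#' @param promoters An [interval_set()] of promoter windows (>= 1 record).
#' @param peaks An [interval_set()] of binding intervals whose `name` column
#'   holds the factor.
#' @return Alphabetically sorted character vector of qualifying factor names.
#' @export
factors_binding_all <- function(promoters, peaks) {
  stopifnot(inherits(promoters, "interval_set"), inherits(peaks, "interval_set"))
  if (nrow(promoters) == 0) stop("empty promoter set", call. = FALSE)
  ov <- intersect_intervals(promoters, peaks)
  n_prom <- nrow(promoters)
  covered <- tapply(ov$index_a, ov$name_b, function(i) length(unique(i)))
  sort(names(covered)[covered == n_prom])
}
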