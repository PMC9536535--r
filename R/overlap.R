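#' Replicate-set concordance
#'
#' Correlation between the log2 effects of two independently processed
#' replicate sets of the same condition, over the genes detected in both —
#' the screen's quality-control view of replicate robustness.
#'
#' @param effects_a,effects_b Named numeric vectors of per-gene log2 effects
#'   over the same detected-gene universe.
#' @param method `"pearson"` (default, matching log2-effect scatter plots) or
#'   `"spearman"`.
#' @return List with `r` (correlation), `n` (shared genes), `method`, and
#'   `table` (per-gene paired data frame for plotting).
#' @export
replicate_concordance <- function(effects_a, effects_b,
                                  method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (is.null(names(effects_a)) || is.null(names(effects_b)))
    stop("effect vectors must be named by gene", call. = FALSE)
  shared <- intersect(names(effects_a), names(effects_b))
  if (length(shared) < 3)
    stop("fewer than 3 shared detected genes", call. = FALSE)
  a <- effects_a[shared]
  b <- effects_b[shared]
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("zero variance in an effect vector", call. = FALSE)
  list(r = stats::cor(a, b, method = method),
       n = length(shared),
       method = method,
       table = data.frame(gene = shared, effect_a = unname(a),
                          effect_b = unname(b), stringsAsFactors = FALSE))
}

#' Upper-tail exact hypergeometric overlap probability
#'
#' P(X >= k) for the overlap k of two sets of sizes `size_a` and `size_b`
#' drawn from a universe of `universe` genes.
#'
#' @param k Observed overlap.
#' @param size_a,size_b Set sizes.
#' @param universe Universe size.
#' @return The exact tail probability in (0, 1].
#' @export
hyper_overlap_p <- function(k, size_a, size_b, universe) {
  if (size_a > universe || size_b > universe)
    stop("universe smaller than a set", call. = FALSE)
  if (k > min(size_a, size_b)) stop("overlap exceeds the smaller set", call. = FALSE)
  stats::phyper(k - 1, size_a, universe - size_a, size_b, lower.tail = FALSE)
}

#' Shared HITS between condition pairs
#'
#' For every pair of conditions, the overlap of their hit gene sets, the
#' Jaccard index, and an upper-tail exact hypergeometric p-value over the
#' detected-gene universe. In sign-aware mode (default) a gene is shared only
#' when both conditions move it in the same direction. The significance test
#' is an addition of this pipeline, not a published procedure, and outputs are
#' labelled accordingly.
#'
#' @param hits Hit data frame from [call_hits()].
#' @param universe Character vector of detected genes (the only genes that can
#'   be HITS).
#' @param direction_mode `"sign_aware"` (default) or `"sign_agnostic"`.
#' @param tier Tiers counted as hits (default `"hit"`).
#' @return Data frame with one row per condition pair: sizes, `n_shared`,
#'   `jaccard`, `p_value`, and the shared genes (comma-separated).
#' @export
shared_hits <- function(hits, universe,
                        direction_mode = c("sign_aware", "sign_agnostic"),
                        tier = "hit") {
  direction_mode <- match.arg(direction_mode)
  h <- hits[hits$tier %in% tier, , drop = FALSE]
  outside <- setdiff(unique(h$gene), universe)
  if (length(outside))
    stop("hit gene(s) outside the universe: ",
         paste(utils::head(outside, 5), collapse = ", "), call. = FALSE)
  conds <- sort(unique(h$condition))
  if (length(conds) < 2)
    stop("need hit sets for at least two conditions", call. = FALSE)
  n_univ <- length(unique(universe))
  per_cond <- split(h, h$condition)
  pairs <- utils::combn(conds, 2, simplify = FALSE)
  rows <- lapply(pairs, function(p) {
    a <- per_cond[[p[1]]]
    b <- per_cond[[p[2]]]
    genes_a <- unique(a$gene)
    genes_b <- unique(b$gene)
    if (direction_mode == "sign_aware") {
      ka <- paste(a$gene, a$direction)
      kb <- paste(b$gene, b$direction)
      shared <- a$gene[ka %in% kb]
    } else {
      shared <- intersect(genes_a, genes_b)
    }
    shared <- sort(unique(shared))
    k <- length(shared)
    union_n <- length(union(genes_a, genes_b))
    data.frame(condition_a = p[1], condition_b = p[2],
               n_a = length(genes_a), n_b = length(genes_b),
               n_shared = k, universe = n_univ,
               jaccard = if (union_n > 0) k / union_n else 0,
               p_value = hyper_overlap_p(k, length(genes_a), length(genes_b), n_univ),
               shared_genes = paste(shared, collapse = ","),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res[order(res$p_value, res$condition_a, res$condition_b), , drop = FALSE]
}

#' Read gene sets from a GMT file
#'
#' Tab-delimited: set name, description, then member genes.
#'
#' @param path Path to a GMT file.
#' @return Named list of character vectors; descriptions in the
#'   `"description"` attribute.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty GMT file: ", path, call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3)
  if (length(bad))
    stop("GMT line(s) with fewer than 3 fields: ", paste(bad, collapse = ", "),
         call. = FALSE)
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[[`, "", 1)
  attr(sets, "description") <- stats::setNames(vapply(fields, `[[`, "", 2), names(sets))
  sets
}

#' Gene-set overlap enrichment for one hit set
#'
#' One exact upper-tail hypergeometric test per gene set against the
#' detected-gene universe (sets are first intersected with the universe), with
#' Benjamini-Hochberg adjustment across sets. A lightweight overlap utility
#' for user-supplied GMT collections.
#'
#' @param hit_genes Character vector of hit genes (must lie in the universe).
#' @param gene_sets Named list of character vectors, e.g. from [read_gmt()].
#' @param universe Character vector of detected genes.
#' @return Data frame, one row per set, sorted by p-value: set sizes, overlap,
#'   `p_value`, BH `q_value`, overlapping genes.
#' @export
gene_set_overlap <- function(hit_genes, gene_sets, universe) {
  if (!length(gene_sets)) stop("empty gene-set collection", call. = FALSE)
  universe <- unique(universe)
  hit_genes <- unique(hit_genes)
  outside <- setdiff(hit_genes, universe)
  if (length(outside))
    stop("hit gene(s) outside the universe: ",
         paste(utils::head(outside, 5), collapse = ", "), call. = FALSE)
  n_univ <- length(universe)
  rows <- lapply(names(gene_sets), function(nm) {
    members <- intersect(unique(gene_sets[[nm]]), universe)
    ov <- sort(intersect(members, hit_genes))
    data.frame(set = nm,
               n_set = length(members),
               n_hits = length(hit_genes),
               n_overlap = length(ov),
               universe = n_univ,
               p_value = hyper_overlap_p(length(ov), length(members),
                                         length(hit_genes), n_univ),
               overlap_genes = paste(ov, collapse = ","),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$q_value <- stats::p.adjust(res$p_value, method = "BH")
  res <- res[order(res$p_value, res$set), , drop = FALSE]
  rownames(res) <- NULL
  res[, c("set", "n_set", "n_hits", "n_overlap", "universe",
          "p_value", "q_value", "overlap_genes")]
}
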