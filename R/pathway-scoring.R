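# Single-sample pathway enrichment: a rank-weighted running-sum statistic
# (ssGSEA) computed strictly per sample. Because only within-sample gene
# ranks enter the computation, scores are invariant under any strictly
# increasing transform of a sample's expression values -- the property that
# makes the downstream classifier platform-independent and normalization-free.

#' Within-sample descending expression ranks
#'
#' Rank 1 is the highest-expressed gene; ties receive the average of the
#' ranks they occupy. An all-constant sample is valid (every rank is
#' (N+1)/2) but flagged with a warning.
#'
#' @param sample_values numeric vector, one expression value per gene.
#' @return numeric rank vector of the same length.
#' @export
rank_genes <- function(sample_values) {
  if (length(sample_values) < 2L) stop_named("need at least 2 genes to rank")
  if (anyNA(sample_values)) stop_named("missing expression values")
  if (length(unique(sample_values)) == 1L) {
    warning("all expression values identical; every rank is (N+1)/2",
            call. = FALSE)
  }
  rank(-sample_values, ties.method = "average")
}

# Positions in the descending-expression ordering used for the running sum.
# ties.method = "first" keeps the traversal deterministic and stable under
# monotone transforms (ties stay ties, original order preserved).
gene_positions <- function(sample_values) {
  rank(-sample_values, ties.method = "first")
}

#' Single-sample enrichment score (ssGSEA) for one gene set
#'
#' Genes are ordered by descending expression. Walking down that list, the
#' score accumulates the difference between a rank-weighted in-set ECDF
#' (weights \eqn{(N - rank + 1)^\alpha}) and the uniform out-of-set ECDF:
#' \deqn{ES = \sum_{i=1}^{N} [P^w_{in}(i) - P_{out}(i)]}
#' The sum is evaluated in closed form (each gene's step contributes once per
#' position at or after it), which equals the explicit running sum exactly.
#'
#' @param sample_values named numeric vector: the sample's expression over the
#'   whole gene universe.
#' @param genes character vector of gene ids forming the set.
#' @param alpha rank-weight exponent, >= 0 (default 0.25).
#' @return the enrichment score (a single number).
#' @export
ssgsea_score <- function(sample_values, genes, alpha = 0.25) {
  check_number(alpha, "alpha", lower = 0)
  universe <- names(sample_values)
  if (is.null(universe)) stop_named("sample_values must be named by gene id")
  idx <- which(universe %in% genes)
  N <- length(sample_values)
  s <- length(idx)
  if (s == 0L) stop_named("gene set has no overlap with the gene universe")
  if (s == N) stop_named("gene set covers the entire gene universe; out-of-set ECDF undefined")
  pos <- gene_positions(sample_values)
  avg <- rank(-sample_values, ties.method = "average")
  w <- (N - avg[idx] + 1)^alpha
  u <- N - pos[idx] + 1
  sum(w * u) / sum(w) - (N * (N + 1) / 2 - sum(u)) / (N - s)
}

#' Pathway score matrix for a cohort
#'
#' Applies [ssgsea_score()] to every admitted gene set and every sample.
#' Each column depends only on that sample's expression vector. Sets whose
#' intersection with the gene universe falls outside `[min_size, max_size]`
#' are dropped and listed in the `dropped` manifest; genes absent from the
#' universe are simply absent from the intersection.
#'
#' @param expr validated expression matrix (genes x samples).
#' @param sets a `gene_set_collection`.
#' @param alpha rank-weight exponent (default 0.25).
#' @param min_size,max_size admitted set size after intersection with the
#'   gene universe (defaults 5 and 2000).
#' @return object of class `pathway_scores`: list with `scores`
#'   (pathways x samples matrix), `alpha`, `min_size`, `max_size` and the
#'   `dropped` manifest (data.frame: set, reason, overlap).
#' @export
compute_pathway_scores <- function(expr, sets, alpha = 0.25,
                                   min_size = 5L, max_size = 2000L) {
  expr <- as_expression_matrix(expr)
  stopifnot(inherits(sets, "gene_set_collection"))
  check_number(alpha, "alpha", lower = 0)
  universe <- rownames(expr)
  N <- nrow(expr)
  overlap <- lapply(sets$sets, function(g) which(universe %in% g))
  sizes <- lengths(overlap)
  reason <- rep(NA_character_, length(sizes))
  reason[sizes < min_size] <- "below_min_size"
  reason[sizes > max_size] <- "above_max_size"
  reason[sizes == N] <- "covers_universe"
  keep <- is.na(reason)
  dropped <- data.frame(set = names(sets$sets)[!keep],
                        reason = reason[!keep],
                        overlap = sizes[!keep],
                        stringsAsFactors = FALSE)
  if (!any(keep)) stop_named("no gene set admitted by the size filter")

  # per-sample ranks, computed once: positions (ties first) drive the running
  # sum, average ranks drive the weights
  POS <- apply(expr, 2L, function(v) rank(-v, ties.method = "first"))
  AVG <- apply(expr, 2L, function(v) rank(-v, ties.method = "average"))
  U <- N - POS + 1
  W <- (N - AVG + 1)^alpha
  total <- N * (N + 1) / 2

  kept <- which(keep)
  scores <- matrix(NA_real_, nrow = length(kept), ncol = ncol(expr),
                   dimnames = list(names(sets$sets)[kept], colnames(expr)))
  for (r in seq_along(kept)) {
    idx <- overlap[[kept[r]]]
    s <- length(idx)
    u <- U[idx, , drop = FALSE]
    w <- W[idx, , drop = FALSE]
    scores[r, ] <- colSums(w * u) / colSums(w) -
      (total - colSums(u)) / (N - s)
  }
  structure(list(scores = scores, alpha = alpha,
                 min_size = min_size, max_size = max_size,
                 dropped = dropped),
            class = "pathway_scores")
}

#' @export
print.pathway_scores <- function(x, ...) {
  cat(sprintf("pathway_scores: %d pathways x %d samples (alpha = %g, %d sets dropped)\n",
              nrow(x$scores), ncol(x$scores), x$alpha, nrow(x$dropped)))
  invisible(x)
}

#' Write a pathway score matrix and its dropped-set manifest as TSV
#' @param ps a `pathway_scores` object.
#' @param path score TSV path; the manifest goes to `<path>.dropped.tsv`.
#' @export
write_pathway_scores <- function(ps, path) {
  stopifnot(inherits(ps, "pathway_scores"))
  df <- data.frame(pathway = rownames(ps$scores), ps$scores,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(ps$dropped, paste0(path, ".dropped.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
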