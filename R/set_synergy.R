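# Set-theoretic complementarity between scoring functions.
#
# Each metric defines a "found set": the benchmark complexes for which it
# places a near-native (class >= q) in its top-N cluster representatives.
# Pairwise union / symmetric difference / relative complement cardinalities
# quantify how differently two metrics succeed; complete-linkage clustering
# on the symmetric-difference cardinalities groups metrics that find the
# same complexes, with cophenetic distances read off the dendrogram.

#' Found set of a metric
#'
#' @inheritParams success_counts
#' @return Object of class `found_set`: list with `metric`, `N`, `q`,
#'   `cases` (character vector of case ids).
#' @export
found_set <- function(results, metric, N = 10, q = "acceptable") {
  hit <- vapply(results, case_found, logical(1), metric = metric, N = N, q = q)
  structure(list(metric = metric, N = N, q = q,
                 cases = vapply(results[hit], `[[`, "", "case_id")),
            class = "found_set")
}

#' Pairwise set cardinalities
#'
#' @param a,b [found_set] objects computed under the same criterion.
#' @return List: `union`, `symdiff`, `a_minus_b`, `b_minus_a`,
#'   `intersection`.
#' @export
pair_cardinalities <- function(a, b) {
  if (!identical(c(a$N, a$q), c(b$N, b$q)))
    stop("found sets computed under different criteria")
  A <- unique(a$cases); B <- unique(b$cases)
  int <- length(intersect(A, B))
  list(union = length(union(A, B)),
       symdiff = length(A) + length(B) - 2L * int,
       a_minus_b = length(A) - int,
       b_minus_a = length(B) - int,
       intersection = int)
}

#' Complete-linkage clustering with cophenetic distances
#'
#' Agglomerative clustering where the distance between clusters is the
#' maximum pairwise dissimilarity; the cophenetic distance of two items is
#' the merge height at which they first share a cluster.
#'
#' @param dissimilarity Symmetric non-negative matrix with zero diagonal
#'   and dimnames.
#' @return List: `hclust` (a [stats::hclust] tree), `cophenetic` (full
#'   matrix), `order` (leaf order), `labels`.
#' @export
complete_linkage <- function(dissimilarity) {
  m <- as.matrix(dissimilarity)
  if (nrow(m) < 2L) stop("need at least 2 items to cluster")
  if (max(abs(m - t(m))) > 1e-12 || any(m < 0) || any(diag(m) != 0))
    stop("dissimilarity must be symmetric, non-negative, zero-diagonal")
  if (is.null(rownames(m))) rownames(m) <- colnames(m) <- paste0("m", seq_len(nrow(m)))
  hc <- stats::hclust(stats::as.dist(m), method = "complete")
  coph <- as.matrix(stats::cophenetic(hc))
  coph <- coph[rownames(m), rownames(m)]
  list(hclust = hc, cophenetic = coph, order = hc$order,
       labels = rownames(m))
}

#' Write a dendrogram as Newick text
#'
#' Branch lengths are merge-height increments, so root-to-leaf path
#' lengths reproduce the merge heights.
#'
#' @param cl Result of [complete_linkage].
#' @param path Output file.
#' @export
write_dendrogram_newick <- function(cl, path) {
  ape::write.tree(ape::as.phylo(cl$hclust), file = path)
  invisible(path)
}

#' Pairwise synergy matrices over a metric panel
#'
#' Builds the symmetric-difference, union and relative-complement
#' cardinality matrices of the metrics' found sets.  The symmetric
#' difference and union matrices are ordered by complete-linkage
#' clustering (symmetric difference as dissimilarity; for the union
#' matrix, `max(union) - union` by default, or the symmetric-difference
#' ordering via `union_ordering = "symdiff"`).  The asymmetric
#' relative-complement matrix (entry `[i, j]` = cases found by i but not
#' j) is ordered by individual top-N success rate, descending.
#'
#' @inheritParams success_table
#' @param N Rank depth of the found-set criterion (default 10).
#' @param q Quality threshold of the criterion (default `"acceptable"`).
#' @param union_ordering `"union"` or `"symdiff"` (see above).
#' @return List: `symdiff`, `union`, `relative_complement` (matrices in
#'   their display orders), `dendrogram` ([complete_linkage] of the
#'   symmetric difference), `union_dendrogram`, `found_sets`,
#'   `success_order`.
#' @export
synergy_matrices <- function(results, metrics = NULL, N = 10,
                             q = "acceptable",
                             union_ordering = c("union", "symdiff")) {
  union_ordering <- match.arg(union_ordering)
  if (is.null(metrics)) metrics <- names(results[[1]]$ranked)
  if (length(metrics) < 2L) stop("need at least 2 metrics")
  fs <- lapply(metrics, function(m) found_set(results, m, N, q))
  names(fs) <- metrics
  k <- length(metrics)
  sym <- uni <- matrix(0, k, k, dimnames = list(metrics, metrics))
  rel <- matrix(0L, k, k, dimnames = list(metrics, metrics))
  for (i in seq_len(k)) {
    uni[i, i] <- length(fs[[i]]$cases)
    for (j in seq_len(k)) {
      if (i == j) next
      pc <- pair_cardinalities(fs[[i]], fs[[j]])
      sym[i, j] <- pc$symdiff
      uni[i, j] <- pc$union
      rel[i, j] <- pc$a_minus_b
    }
  }
  dend <- complete_linkage(sym)
  ord_sym <- dend$labels[dend$order]
  uni_diss <- max(uni) - uni
  diag(uni_diss) <- 0
  uni_dend <- complete_linkage(uni_diss)
  ord_uni <- if (union_ordering == "union") uni_dend$labels[uni_dend$order]
             else ord_sym
  rate <- vapply(fs, function(f) length(f$cases), integer(1))
  ord_rate <- metrics[order(-rate, seq_along(metrics))]
  list(symdiff = sym[ord_sym, ord_sym],
       union = uni[ord_uni, ord_uni],
       relative_complement = rel[ord_rate, ord_rate],
       dendrogram = dend, union_dendrogram = uni_dend,
       found_sets = fs, success_order = ord_rate)
}
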