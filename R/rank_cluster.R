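# Re-ranking and greedy leader clustering of docked poses.
#
# Decoys are sorted best-first by one metric (ascending for energies,
# descending for count-like scores), then swept in that order: each pose
# joins the first existing cluster whose LEADER is within the RMSD
# threshold, otherwise it founds a new cluster.  Only cluster leaders
# survive into the ranked list, following the convention of discarding all
# but the lowest-energy member of each 3-angstrom cluster.

#' Re-rank decoys by one metric
#'
#' @param score_table Result of [score_decoy_set] (or [read_score_table]).
#' @param metric A [metric_spec], or a metric name (then `direction` is
#'   consulted).
#' @param direction Used when `metric` is a plain name.
#' @return data.frame `decoy_id`, `score`, best first; missing scores are
#'   excluded; ties keep stable input order.
#' @export
rerank <- function(score_table, metric, direction = "ascending_better") {
  if (inherits(metric, "metric_spec")) {
    direction <- metric$direction
    metric <- metric$name
  }
  if (!metric %in% names(score_table)) stop("metric not in score table: ", metric)
  s <- score_table[[metric]]
  keep <- !is.na(s)
  if (!any(keep)) {
    warning("all scores missing for metric ", metric)
    return(data.frame(decoy_id = character(0), score = numeric(0)))
  }
  ids <- score_table$decoy_id[keep]
  s <- s[keep]
  key <- if (direction == "descending_better") -s else s
  o <- order(key, seq_along(key))   # stable ties
  data.frame(decoy_id = ids[o], score = s[o], stringsAsFactors = FALSE)
}

#' Pairwise pose-distance function for a decoy set
#'
#' Returns a function `d(id_a, id_b)` giving the ligand backbone RMSD
#' between two decoys after superposing their receptor backbones (the
#' same frame-then-ligand construction as LRMSD, with a decoy instead of
#' the native as reference).  With `metric = "complex_rmsd"` the full
#' backbone RMSD after whole-complex superposition is used instead.
#'
#' @param ds A [decoy_set].
#' @param metric `"ligand_rmsd"` (default) or `"complex_rmsd"`.
#' @return Function of two decoy ids.
#' @export
make_pose_distance <- function(ds, metric = c("ligand_rmsd", "complex_rmsd")) {
  metric <- match.arg(metric)
  rec <- lapply(ds$decoys, function(d) bb_select(d, ds$partition$receptor))
  lig <- lapply(ds$decoys, function(d) bb_select(d, ds$partition$ligand))
  if (metric == "ligand_rmsd") {
    function(id_a, id_b) {
      pr <- pair_bb(rec[[id_a]], rec[[id_b]])
      sup <- kabsch_superpose(pr$ref, pr$mov)
      pl <- pair_bb(lig[[id_a]], lig[[id_b]])
      rmsd_between(apply_superposition(pl$mov, sup), pl$ref)
    }
  } else {
    function(id_a, id_b) {
      pa <- pair_bb(list(key = c(rec[[id_a]]$key, lig[[id_a]]$key),
                         xyz = rbind(rec[[id_a]]$xyz, lig[[id_a]]$xyz)),
                    list(key = c(rec[[id_b]]$key, lig[[id_b]]$key),
                         xyz = rbind(rec[[id_b]]$xyz, lig[[id_b]]$xyz)))
      kabsch_superpose(pa$ref, pa$mov)$rmsd
    }
  }
}

#' Greedy leader clustering of ranked poses
#'
#' Visits decoys best-first; a decoy joins the first (best-ranked) cluster
#' whose leader is within `threshold`, else founds a new cluster.
#'
#' @param ranked data.frame from [rerank].
#' @param pose_distance Function of two decoy ids (see
#'   [make_pose_distance]); must be symmetric, non-negative and zero on
#'   identical poses.
#' @param threshold Clustering radius in angstroms (default 3).
#' @return List of clusters, each `list(leader, members)`; cluster order
#'   is leader score order.
#' @export
greedy_cluster <- function(ranked, pose_distance, threshold = 3) {
  clusters <- list()
  leaders <- character(0)
  for (id in ranked$decoy_id) {
    placed <- FALSE
    for (k in seq_along(leaders)) {
      if (pose_distance(leaders[k], id) <= threshold) {
        clusters[[k]]$members <- c(clusters[[k]]$members, id)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      leaders <- c(leaders, id)
      clusters[[length(clusters) + 1L]] <- list(leader = id, members = id)
    }
  }
  clusters
}

#' Ranked list of cluster representatives
#'
#' @param clusters Result of [greedy_cluster].
#' @param ranked The [rerank] table the clusters came from (for scores).
#' @param quality [quality_table] rows for the same decoys.
#' @return data.frame `rank`, `decoy_id`, `score`, `fnat`, `irmsd`,
#'   `lrmsd`, `class` — one row per cluster leader, in score order.
#' @export
representatives <- function(clusters, ranked, quality) {
  leaders <- vapply(clusters, `[[`, "", "leader")
  qi <- match(leaders, quality$decoy_id)
  if (any(is.na(qi))) stop("quality label missing for leader(s): ",
                           paste(leaders[is.na(qi)], collapse = ","))
  data.frame(rank = seq_along(leaders), decoy_id = leaders,
             score = ranked$score[match(leaders, ranked$decoy_id)],
             fnat = quality$fnat[qi], irmsd = quality$irmsd[qi],
             lrmsd = quality$lrmsd[qi],
             class = quality$class[qi],
             stringsAsFactors = FALSE)
}

#' Rank, cluster and label one case for one metric
#'
#' Convenience wrapper: [rerank] then [greedy_cluster] then
#' [representatives].
#'
#' @param ds A [decoy_set].
#' @param score_table From [score_decoy_set].
#' @param metric A [metric_spec] or metric name.
#' @param quality From [quality_table].
#' @param threshold Cluster radius in angstroms.
#' @param direction Score direction when `metric` is a plain name.
#' @param pose_distance Optional precomputed distance function (shared
#'   across metrics of the same case to avoid recomputation).
#' @return A representatives data.frame (the per-case ranked list).
#' @export
rank_case <- function(ds, score_table, metric, quality, threshold = 3,
                      direction = "ascending_better", pose_distance = NULL) {
  ranked <- rerank(score_table, metric, direction)
  if (nrow(ranked) == 0L) return(representatives(list(), ranked, quality))
  if (is.null(pose_distance)) pose_distance <- make_pose_distance(ds)
  representatives(greedy_cluster(ranked, pose_distance, threshold),
                  ranked, quality)
}
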