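# Benchmark-level evaluation: top-N success rates, conditional success
# probabilities, and difficulty-stratified variants.
#
# The unit of analysis is a `case_result`: one benchmark complex with its
# per-metric ranked lists of cluster representatives and the best quality
# available among ALL generated decoys (pre-clustering), which defines the
# denominator for conditional probabilities.

DIFFICULTY_LEVELS <- c("rigid_body", "medium", "difficult")

#' Bundle one case's evaluation inputs
#'
#' @param case_id Case identifier.
#' @param ranked Named list (metric -> representatives data.frame from
#'   [rank_case]).
#' @param best_available Best CAPRI class among all generated decoys
#'   (character or factor level).
#' @param difficulty One of `"rigid_body"`, `"medium"`, `"difficult"`.
#' @return Object of class `case_result`.
#' @export
case_result <- function(case_id, ranked, best_available,
                        difficulty = "rigid_body") {
  difficulty <- match.arg(difficulty, DIFFICULTY_LEVELS)
  best_available <- factor(as.character(best_available),
                           levels = QUALITY_LEVELS, ordered = TRUE)
  structure(list(case_id = case_id, ranked = ranked,
                 best_available = best_available, difficulty = difficulty),
            class = "case_result")
}

#' Evaluate one case end-to-end
#'
#' Runs quality computation, scoring, ranking and clustering for every
#' metric, producing the [case_result] consumed by the benchmark
#' statistics.
#'
#' @param ds A [decoy_set].
#' @param metrics List of [metric_spec].
#' @param difficulty Case difficulty label.
#' @param threshold Cluster radius in angstroms.
#' @param score_table Optional precomputed score table (externally
#'   computed metrics); computed from `metrics` when `NULL`.
#' @param quality Optional precomputed [quality_table].
#' @return A [case_result].
#' @export
evaluate_case <- function(ds, metrics, difficulty = "rigid_body",
                          threshold = 3, score_table = NULL, quality = NULL) {
  if (is.null(quality)) quality <- quality_table(ds)
  if (is.null(score_table)) score_table <- score_decoy_set(ds, metrics)
  pd <- make_pose_distance(ds)
  ranked <- lapply(metrics, function(m)
    rank_case(ds, score_table, m, quality, threshold, pose_distance = pd))
  names(ranked) <- vapply(metrics, `[[`, "", "name")
  case_result(ds$case_id, ranked, max(quality$class), difficulty)
}

as_quality <- function(q) {
  if (is.character(q)) factor(q, levels = QUALITY_LEVELS, ordered = TRUE)[[1]]
  else q
}

# TRUE when the case's top-N representatives for `metric` include a pose
# of class >= q.
case_found <- function(cr, metric, N, q) {
  rl <- cr$ranked[[metric]]
  if (is.null(rl)) stop("metric not evaluated for case ", cr$case_id, ": ", metric)
  top <- rl[rl$rank <= N, , drop = FALSE]
  nrow(top) > 0L && any(top$class >= as_quality(q))
}

#' Top-N success count
#'
#' Number of cases for which a pose of at least quality `q` appears among
#' the top `N` ranked cluster representatives of `metric`.
#'
#' @param results List of [case_result].
#' @param metric Metric name.
#' @param N Rank depth (1, 10, 100, ...).
#' @param q Quality threshold (`"acceptable"`, `"medium"`, `"high"`).
#' @return Integer count.
#' @export
success_counts <- function(results, metric, N, q = "acceptable") {
  sum(vapply(results, case_found, logical(1), metric = metric, N = N, q = q))
}

#' Success-rate table for a set of metrics
#'
#' @param results List of [case_result].
#' @param metrics Character vector of metric names (default: all metrics
#'   of the first case).
#' @param N Rank depths.
#' @param q Quality thresholds.
#' @param denominator `"all"` divides by the number of cases (headline
#'   success rates); `"available"` divides by the number of cases where a
#'   pose of at least `q` exists among all generated decoys.
#' @return data.frame: `metric`, `N`, `quality`, `count`, `denominator`,
#'   `rate`, `percent` (nearest integer).
#' @export
success_table <- function(results, metrics = NULL, N = c(1, 10, 100),
                          q = c("acceptable", "medium", "high"),
                          denominator = c("all", "available")) {
  denominator <- match.arg(denominator)
  if (is.null(metrics)) metrics <- names(results[[1]]$ranked)
  grid <- expand.grid(metric = metrics, N = N, quality = q,
                      stringsAsFactors = FALSE)
  best <- do.call(c, lapply(results, function(cr) cr$best_available))
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    den <- if (denominator == "all") length(results)
           else sum(best >= as_quality(g$quality))
    cnt <- success_counts(results, g$metric, g$N, g$quality)
    data.frame(metric = g$metric, N = g$N, quality = g$quality, count = cnt,
               denominator = den,
               rate = if (den > 0) cnt / den else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$percent <- format_percent(out$count, out$denominator)
  out
}

#' Percentage to the nearest integer
#'
#' The reporting convention used throughout: `round(100 * num / den)`,
#' e.g. 76/115 -> 66.
#'
#' @param num,den Numerator and denominator.
#' @return Integer percent (NA when `den` is 0).
#' @export
format_percent <- function(num, den) {
  ifelse(den > 0, as.integer(round(100 * num / den)), NA_integer_)
}

#' Conditional probability of finding a solution given one exists
#'
#' P(a pose of class >= q appears in the metric's top N | a pose of class
#' >= q exists among all generated decoys for the case).
#'
#' @inheritParams success_counts
#' @return List: `value` (fraction), `count`, `denominator`.  `value` is
#'   `NA` with a warning when no case has a pose of class >= q.
#' @export
conditional_probability <- function(results, metric, N = 10, q = "acceptable") {
  have <- vapply(results, function(cr) cr$best_available >= as_quality(q),
                 logical(1))
  den <- sum(have)
  if (den == 0L) {
    warning("no case has a pose of quality >= ", q,
            "; conditional probability undefined")
    return(list(value = NA_real_, count = 0L, denominator = 0L))
  }
  cnt <- success_counts(results[have], metric, N, q)
  list(value = cnt / den, count = cnt, denominator = den)
}

#' Difficulty-stratified success tables
#'
#' Rigid-body cases form one stratum; medium and difficult cases are
#' pooled into a `flexible` stratum (they are fewer, and near-native
#' poses are rarer there).
#'
#' @inheritParams success_table
#' @return Named list of [success_table] data.frames:
#'   `rigid_body`, `flexible`.
#' @export
stratify <- function(results, metrics = NULL, N = c(1, 10, 100),
                     q = c("acceptable", "medium", "high"),
                     denominator = c("all", "available")) {
  diff <- vapply(results, `[[`, "", "difficulty")
  if (any(!diff %in% DIFFICULTY_LEVELS)) stop("unlabelled case difficulty")
  rigid <- results[diff == "rigid_body"]
  flex <- results[diff != "rigid_body"]
  if (length(flex) == 0L) warning("no medium/difficult cases in benchmark")
  tab <- function(rs) {
    if (length(rs) == 0L) return(NULL)
    success_table(rs, metrics, N, q, denominator)
  }
  list(rigid_body = tab(rigid), flexible = tab(flex))
}
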