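#' Contiguous-subsequence test for vertex paths
#'
#' @param query,target Integer vertex sequences.
#' @return `TRUE` iff `query` occurs as a contiguous subsequence of
#'   `target` (a path is "correct" when it is a subpath of some ground
#'   truth transcript).
#' @export
is_subpath <- function(query, target) {
  lq <- length(query); lt <- length(target)
  if (lq == 0L || lq > lt) return(FALSE)
  if (lq == 1L) return(query %in% target)
  grepl(seq_key(query), seq_key(target), fixed = TRUE)
}

strip_artificial <- function(vseq, artificial) {
  if (length(artificial) == 0L) vseq else vseq[!(vseq %in% artificial)]
}

path_len <- function(vseq, unit, node_lengths) {
  if (length(vseq) == 0L) return(0)
  if (unit == "node") length(vseq) else sum(node_lengths[vseq])
}

check_metric_graph <- function(g, reported) {
  if (anyDuplicated(paste(g$edges$from, g$edges$to)) > 0L)
    stop("metrics are defined on vertex sequences; graphs with parallel edges are not supported")
  bad <- unlist(reported)[!(unlist(reported) %in% seq_len(g$n))]
  if (length(bad) > 0L)
    stop("reported path mentions unknown vertex ", bad[1])
  invisible(NULL)
}

#' Weighted precision
#'
#' A reported path is correct if (after removing artificial source/sink
#' vertices) it is a subpath of some ground-truth transcript. Weighted
#' precision is the total length of correct reported paths divided by the
#' total length of all reported paths, where length counts vertices
#' (`unit = "node"`) or sums their base lengths (`unit = "base"`). An empty
#' report is vacuously correct (precision 1).
#'
#' @param reported List of integer vertex sequences.
#' @param truth List of transcripts: integer vertex sequences, or
#'   `list(vertices, weight)` records.
#' @param unit `"node"` or `"base"`.
#' @param node_lengths Per-vertex base counts (required for `unit = "base"`).
#' @param artificial Vertex ids to strip before comparison (the global
#'   source/sink added when superimposing transcripts).
#' @return A fraction in \[0, 1\].
#' @examples
#' truth <- list(c(1, 2, 3, 4, 5))       # s, three exons, t
#' weighted_precision(list(c(2, 3), c(2, 4)), truth, artificial = c(1, 5))
#' @export
weighted_precision <- function(reported, truth, unit = c("node", "base"),
                               node_lengths = NULL, artificial = integer(0)) {
  unit <- match.arg(unit)
  if (unit == "base" && is.null(node_lengths))
    stop("base-unit metrics require node_lengths")
  truth <- lapply(truth, truth_vertices)
  truth <- lapply(truth, strip_artificial, artificial = artificial)
  reported <- lapply(reported, strip_artificial, artificial = artificial)
  reported <- reported[lengths(reported) > 0L]
  if (length(reported) == 0L) return(1)
  lens <- vapply(reported, path_len, numeric(1), unit = unit,
                 node_lengths = node_lengths)
  correct <- vapply(reported, function(r)
    any(vapply(truth, function(t) is_subpath(r, t), logical(1))), logical(1))
  sum(lens[correct]) / sum(lens)
}

truth_vertices <- function(t) {
  if (is.list(t)) as.integer(t$vertices) else as.integer(t)
}

# Longest common contiguous stretch between two vertex sequences, measured
# in the requested unit; classic O(|a||b|) run-length DP, row-vectorized.
longest_common_stretch <- function(a, b, unit, node_lengths) {
  la <- length(a); lb <- length(b)
  if (la == 0L || lb == 0L) return(0)
  best <- 0
  cum <- if (unit == "base") c(0, cumsum(node_lengths[b])) else c(0, seq_len(lb))
  prev <- integer(lb)
  for (i in seq_len(la)) {
    hit <- a[i] == b
    cur <- integer(lb)
    cur[hit] <- c(0L, prev)[which(hit)] + 1L
    if (any(hit)) {
      ends <- which(hit)
      stretch <- cum[ends + 1L] - cum[ends - cur[ends] + 1L]
      best <- max(best, stretch)
    }
    prev <- cur
  }
  best
}

#' Maximum relative coverage
#'
#' For each ground-truth transcript `T`, a *segment* of a reported path `R`
#' inside `T` is a maximal contiguous stretch of `R` that is also a subpath
#' of `T`. The transcript's score is the length of the longest such
#' segment over all reported paths, divided by the length of `T`; segments
#' are never merged across paths or across gaps. The instance value is the
#' mean over transcripts.
#'
#' @inheritParams weighted_precision
#' @return A fraction in \[0, 1\].
#' @export
max_relative_coverage <- function(reported, truth, unit = c("node", "base"),
                                  node_lengths = NULL, artificial = integer(0)) {
  unit <- match.arg(unit)
  if (unit == "base" && is.null(node_lengths))
    stop("base-unit metrics require node_lengths")
  truth <- lapply(truth, truth_vertices)
  truth <- lapply(truth, strip_artificial, artificial = artificial)
  reported <- lapply(reported, strip_artificial, artificial = artificial)
  reported <- reported[lengths(reported) > 0L]
  vals <- vapply(truth, function(t) {
    tl <- path_len(t, unit, node_lengths)
    if (tl == 0) return(0)
    if (length(reported) == 0L) return(0)
    best <- max(vapply(reported, longest_common_stretch, numeric(1),
                       b = t, unit = unit, node_lengths = node_lengths))
    best / tl
  }, numeric(1))
  mean(vals)
}

#' F-score
#'
#' Harmonic mean of weighted precision and maximum relative coverage;
#' defined as 0 when both are 0.
#'
#' @param precision,coverage Fractions in \[0, 1\].
#' @return `2 * p * c / (p + c)`, or 0 if `p + c == 0`.
#' @export
f_score <- function(precision, coverage) {
  ifelse(precision + coverage == 0, 0,
         2 * precision * coverage / (precision + coverage))
}

#' Evaluate one reported path set against an instance's ground truth
#'
#' Computes weighted precision, maximum relative coverage and F-score for
#' a set of reported paths on one splice-graph instance, stripping the
#' instance's artificial source/sink before comparison.
#'
#' @param instance A `splice_instance` (from [simulate_splice_instance()])
#'   or a list with fields `graph`, `truth` (list of
#'   `list(vertices, weight)`), and optionally `node_lengths`.
#' @param reported List of paths, either integer vertex sequences or
#'   edge-id vectors (auto-detected per `reported_as`).
#' @param unit `"node"` or `"base"`.
#' @param reported_as `"vertices"` or `"edges"`.
#' @param algorithm Label recorded in the result row.
#' @return One-row data frame: `name`, `k`, `algorithm`, `unit`,
#'   `precision`, `coverage`, `fscore`.
#' @export
evaluate_instance <- function(instance, reported, unit = c("node", "base"),
                              reported_as = c("vertices", "edges"),
                              algorithm = "reported") {
  unit <- match.arg(unit)
  reported_as <- match.arg(reported_as)
  g <- instance$graph
  if (reported_as == "edges")
    reported <- lapply(reported, function(p) path_vertices(g, p))
  check_metric_graph(g, reported)
  truth <- lapply(instance$truth, truth_vertices)
  artificial <- if (!is.null(g$artificial_st)) g$artificial_st else integer(0)
  nl <- if (!is.null(instance$node_lengths)) instance$node_lengths else g$node_lengths
  p <- weighted_precision(reported, truth, unit, nl, artificial)
  cv <- max_relative_coverage(reported, truth, unit, nl, artificial)
  data.frame(name = g$name, k = length(truth), algorithm = algorithm,
             unit = unit, precision = p, coverage = cv,
             fscore = f_score(p, cv))
}

#' Aggregate per-graph metric rows into dataset summaries
#'
#' Unweighted mean of each metric over graphs, overall and within the
#' complexity strata `k <= k_split` ("simple") and `k > k_split`
#' ("complex"), per algorithm and unit.
#'
#' @param rows Data frame of rows from [evaluate_instance()].
#' @param k_split Stratum boundary (default 10).
#' @return Data frame with columns `stratum`, `algorithm`, `unit`,
#'   `n_graphs`, `coverage`, `precision`, `fscore`.
#' @export
aggregate_metrics <- function(rows, k_split = 10) {
  strata <- list(all = rep(TRUE, nrow(rows)),
                 simple = rows$k <= k_split,
                 complex = rows$k > k_split)
  out <- list()
  for (sname in names(strata)) {
    sub <- rows[strata[[sname]], , drop = FALSE]
    if (nrow(sub) == 0L) next
    for (alg in unique(sub$algorithm)) for (u in unique(sub$unit)) {
      ss <- sub[sub$algorithm == alg & sub$unit == u, , drop = FALSE]
      if (nrow(ss) == 0L) next
      out[[length(out) + 1L]] <- data.frame(
        stratum = sname, algorithm = alg, unit = u, n_graphs = nrow(ss),
        coverage = mean(ss$coverage), precision = mean(ss$precision),
        fscore = mean(ss$fscore))
    }
  }
  do.call(rbind, out)
}
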