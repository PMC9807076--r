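#' Enumerate all source-to-sink paths
#'
#' Depth-first enumeration following out-edges in ascending edge-id order,
#' so the result is in lexicographic edge-id order. Intended for small
#' graphs (tests, oracles, bottleneck checks); the count is exponential in
#' general.
#'
#' @param g A `flow_graph`.
#' @param max_paths Abort if more than this many paths are found.
#' @return List of edge-id vectors.
#' @export
all_st_paths <- function(g, max_paths = 100000L) {
  s <- flow_source(g); t <- flow_sink(g)
  out_edges <- split(seq_len(nrow(g$edges)),
                     factor(g$edges$from, levels = seq_len(g$n)))
  res <- list()
  rec <- function(v, acc) {
    if (v == t) {
      res[[length(res) + 1L]] <<- acc
      if (length(res) > max_paths) stop("too many s-t paths")
      return()
    }
    for (eid in out_edges[[v]]) rec(g$edges$to[eid], c(acc, eid))
  }
  rec(s, integer(0))
  res
}

#' Enumerate all directed paths of a graph
#'
#' All contiguous directed paths with at least one edge, optionally capped
#' at `max_len` edges. Exponential in general; meant for oracle-sized
#' graphs.
#'
#' @param g A `flow_graph`.
#' @param max_len Maximum path length in edges.
#' @return List of edge-id vectors.
#' @export
all_graph_paths <- function(g, max_len = Inf) {
  out_edges <- split(seq_len(nrow(g$edges)),
                     factor(g$edges$from, levels = seq_len(g$n)))
  res <- list()
  rec <- function(v, acc) {
    if (length(acc) > 0L) res[[length(res) + 1L]] <<- acc
    if (length(acc) >= max_len) return()
    for (eid in out_edges[[v]]) rec(g$edges$to[eid], c(acc, eid))
  }
  for (v in seq_len(g$n)) rec(v, integer(0))
  res
}

#' Exhaustively enumerate all integer flow decompositions
#'
#' A flow decomposition assigns a nonnegative integer weight to every
#' source-to-sink path such that, on each edge, the weights of the paths
#' through it sum to the edge's flow. Enumerating weight assignments over
#' the full lexicographic path list (with backtracking and a coverage
#' prune) yields every decomposition exactly once as a multiset — the
#' ground-truth universe against which safety is defined. Exponential; the
#' guard refuses graphs beyond oracle scale.
#'
#' @param g A `flow_graph` in integer mode.
#' @param max_total_flow Guard on total flow `fout(s)` (default 8).
#' @param max_edges Guard on edge count (default 12).
#' @return List with `paths` (list of edge-id vectors) and `weights` (one
#'   row per decomposition, one column per path; zero weight means the path
#'   is absent from that decomposition).
#' @export
all_flow_decompositions <- function(g, max_total_flow = 8, max_edges = 12) {
  if (!g$integer_mode) stop("oracle requires integer weights")
  total <- sum(g$edges$weight[g$edges$from == flow_source(g)])
  m <- nrow(g$edges)
  if (total > max_total_flow || m > max_edges)
    stop(sprintf("oracle guard exceeded (total flow %g > %g or m %d > %d): enumeration is exponential",
                 total, max_total_flow, m, max_edges))
  paths <- all_st_paths(g)
  N <- length(paths)
  # cover[[i]]: logical mask over edges covered by paths i..N
  on_path <- lapply(paths, function(p) {
    z <- logical(m); z[p] <- TRUE; z
  })
  suffix_cover <- vector("list", N + 1L)
  suffix_cover[[N + 1L]] <- logical(m)
  for (i in rev(seq_len(N)))
    suffix_cover[[i]] <- suffix_cover[[i + 1L]] | on_path[[i]]
  sols <- list()
  rec <- function(i, res) {
    if (i > N) {
      if (all(res == 0)) sols[[length(sols) + 1L]] <<- integer(0)
      return()
    }
    if (any(res > 0 & !suffix_cover[[i]])) return()  # uncoverable residual
    b <- min(res[paths[[i]]])
    for (wi in 0:b) {
      res2 <- res
      if (wi > 0) res2[paths[[i]]] <- res2[paths[[i]]] - wi
      before <- length(sols)
      rec(i + 1L, res2)
      if (length(sols) > before)
        for (j in (before + 1L):length(sols))
          sols[[j]] <<- c(wi, sols[[j]])
    }
  }
  rec(1L, g$edges$weight)
  weights <- do.call(rbind, sols)
  if (is.null(weights)) weights <- matrix(0, nrow = 0, ncol = N)
  list(paths = paths, weights = weights)
}

# Smallest, over all decompositions, of the total weight of decomposition
# paths containing `edge_ids` as a contiguous subpath.
oracle_min_cover <- function(decomps, edge_ids) {
  qk <- seq_key(edge_ids)
  covering <- vapply(decomps$paths,
                     function(p) grepl(qk, seq_key(p), fixed = TRUE),
                     logical(1))
  if (!any(covering)) return(0)
  min(decomps$weights[, covering, drop = FALSE] %*% rep(1, sum(covering)))
}

seq_key <- function(ids) paste0(",", paste(ids, collapse = ","), ",")

#' Brute-force safety oracle
#'
#' Decides w-safety directly from its definition: enumerate every integer
#' flow decomposition and check that in each one the decomposition paths
#' containing the query path sum to weight at least `w`. Entirely
#' independent of the excess-flow characterization; used to validate it.
#'
#' @param g A `flow_graph` within the oracle guard.
#' @param edge_ids Query path (contiguous edge ids).
#' @param w Positive integer weight.
#' @param decomps Optional precomputed result of
#'   [all_flow_decompositions()], to amortize the enumeration over many
#'   queries on the same graph.
#' @return `TRUE` iff the path is w-safe.
#' @export
brute_force_safety_oracle <- function(g, edge_ids, w, decomps = NULL) {
  if (w <= 0) stop("w must be positive")
  path_vertices(g, edge_ids)  # validate contiguity
  if (is.null(decomps)) decomps <- all_flow_decompositions(g)
  oracle_min_cover(decomps, edge_ids) >= w
}

#' Oracle-derived set of all maximal safe paths
#'
#' Enumerates every path of the graph, keeps those that are 1-safe
#' according to the brute-force oracle, and discards any safe path that is
#' a contiguous subpath of another safe path. Reference answer for the
#' two-pointer enumeration on guard-sized graphs.
#'
#' @inheritParams brute_force_safety_oracle
#' @return List of edge-id vectors (the maximal safe paths).
#' @export
oracle_maximal_safe_paths <- function(g, decomps = NULL) {
  if (is.null(decomps)) decomps <- all_flow_decompositions(g)
  cand <- all_graph_paths(g)
  safe <- cand[vapply(cand, function(p) oracle_min_cover(decomps, p) >= 1,
                      logical(1))]
  if (length(safe) == 0L) return(list())
  keys <- vapply(safe, seq_key, character(1))
  lens <- lengths(safe)
  keep <- rep(TRUE, length(safe))
  for (i in seq_along(safe)) {
    for (j in seq_along(safe)) {
      if (i != j && lens[j] > lens[i] && grepl(keys[i], keys[j], fixed = TRUE)) {
        keep[i] <- FALSE
        break
      }
    }
    if (keep[i] && i > 1L && keys[i] %in% keys[seq_len(i - 1L)])
      keep[i] <- FALSE
  }
  safe[keep]
}
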