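#' Construct a flow graph
#'
#' A flow graph is a weighted directed acyclic multigraph with a unique
#' source \eqn{s} (no incoming edges), a unique sink \eqn{t} (no outgoing
#' edges), strictly positive edge weights \eqn{f(e)}, and conservation of
#' flow \eqn{f_{in}(v) = f_{out}(v)} at every internal vertex. Vertices are
#' labelled `1..n`; edges are identified by their position (row) in the edge
#' table, so parallel edges are distinguished by edge id. Paths throughout
#' the package are integer vectors of edge ids, never vertex sequences, so
#' that parallel edges are unambiguous.
#'
#' When every weight is a whole number the graph is in *integer mode*: all
#' flow arithmetic (excess flow, decomposition residuals) is then exact,
#' because whole-number doubles are closed under the additions and
#' subtractions performed here. Otherwise comparisons use a relative
#' tolerance.
#'
#' @param n Number of vertices.
#' @param edges A data frame (or matrix) with columns `from`, `to`, `weight`.
#' @param name Optional instance label.
#' @param node_lengths Optional positive base counts per vertex (length `n`).
#' @param validate If `TRUE` (default), reject graphs violating the flow
#'   graph invariants. Set to `FALSE` to build deliberately invalid graphs
#'   for inspection with [validate_flow_graph()].
#' @param augment If `TRUE`, a graph with multiple sources and/or sinks is
#'   repaired by adding a global source/sink connected to each original
#'   source/sink with its full out-/in-flow (mirroring how splice graphs are
#'   built from superimposed transcripts).
#' @param tol Relative conservation tolerance for non-integer weights.
#' @return An object of class `flow_graph`: a list with fields `name`, `n`,
#'   `edges` (data frame `from`, `to`, `weight`), `node_lengths`,
#'   `integer_mode`, and `artificial_st` (vertex ids of an artificial
#'   source/sink pair, or `NULL`).
#' @examples
#' g <- flow_graph(4, data.frame(from = c(1, 2, 1, 3),
#'                               to   = c(2, 4, 3, 4),
#'                               weight = c(1, 1, 2, 2)), name = "diamond")
#' g
#' @export
flow_graph <- function(n, edges, name = "", node_lengths = NULL,
                       validate = TRUE, augment = FALSE, tol = 1e-9) {
  edges <- as.data.frame(edges)
  stopifnot(all(c("from", "to", "weight") %in% names(edges)))
  edges <- data.frame(from = as.integer(edges$from),
                      to = as.integer(edges$to),
                      weight = as.numeric(edges$weight))
  n <- as.integer(n)
  g <- structure(list(name = as.character(name), n = n, edges = edges,
                      node_lengths = node_lengths,
                      integer_mode = nrow(edges) == 0L ||
                        all(edges$weight == round(edges$weight)),
                      artificial_st = NULL),
                 class = "flow_graph")
  if (augment) g <- augment_sources_sinks(g)
  if (validate) {
    rep <- validate_flow_graph(g, tol = tol)
    if (nrow(rep) > 0L)
      stop("invalid flow graph '", g$name, "': ",
           paste(rep$message, collapse = "; "))
  }
  g
}

# Add a global source/sink if the graph has several; each original source u
# gets an edge s -> u carrying fout(u), each original sink v an edge v -> t
# carrying fin(v). New vertices are appended as n+1 (source) and n+2 (sink).
augment_sources_sinks <- function(g) {
  deg <- vertex_degrees(g)
  io <- in_out_flow(g)
  sources <- which(deg$indeg == 0L & deg$outdeg > 0L)
  sinks <- which(deg$outdeg == 0L & deg$indeg > 0L)
  if (length(sources) <= 1L && length(sinks) <= 1L) return(g)
  s <- g$n + 1L
  t <- g$n + 2L
  add <- rbind(
    data.frame(from = s, to = sources, weight = io$fout[sources]),
    data.frame(from = sinks, to = t, weight = io$fin[sinks]))
  g$edges <- rbind(g$edges, add)
  g$n <- g$n + 2L
  if (!is.null(g$node_lengths)) g$node_lengths <- c(g$node_lengths, 0, 0)
  g$artificial_st <- c(s, t)
  g
}

#' @export
print.flow_graph <- function(x, ...) {
  cat(sprintf("<flow_graph '%s': %d vertices, %d edges, total flow %g%s>\n",
              x$name, x$n, nrow(x$edges),
              sum(x$edges$weight[x$edges$from == flow_source(x)]),
              if (x$integer_mode) ", integer" else ""))
  invisible(x)
}

vertex_degrees <- function(g) {
  list(indeg = tabulate(g$edges$to, nbins = g$n),
       outdeg = tabulate(g$edges$from, nbins = g$n))
}

#' Source and sink of a flow graph
#'
#' @param g A `flow_graph`.
#' @return The vertex id of the unique source (no in-edges) or sink (no
#'   out-edges).
#' @export
flow_source <- function(g) {
  deg <- vertex_degrees(g)
  src <- which(deg$indeg == 0L)
  if (length(src) != 1L) stop("graph does not have a unique source")
  src
}

#' @rdname flow_source
#' @export
flow_sink <- function(g) {
  deg <- vertex_degrees(g)
  snk <- which(deg$outdeg == 0L)
  if (length(snk) != 1L) stop("graph does not have a unique sink")
  snk
}

#' Validate a flow graph
#'
#' Checks, without throwing, every invariant of the flow-graph model:
#' acyclicity, vertex indices in range, strictly positive weights, a unique
#' source and sink, and conservation of flow at internal vertices
#' (`|fin(v) - fout(v)| <= tol * max(fin(v), 1)`).
#'
#' @param g A `flow_graph` (possibly built with `validate = FALSE`).
#' @param tol Relative conservation tolerance; ignored in integer mode,
#'   where conservation must hold exactly.
#' @return A data frame with columns `kind` (one of `"range"`, `"weight"`,
#'   `"cycle"`, `"source"`, `"sink"`, `"conservation"`) and `message`;
#'   zero rows means the graph is valid.
#' @examples
#' bad <- flow_graph(4, data.frame(from = c(1, 2, 1, 3), to = c(2, 4, 3, 4),
#'                                 weight = c(1, 2, 2, 2)), validate = FALSE)
#' validate_flow_graph(bad)
#' @export
validate_flow_graph <- function(g, tol = 1e-9) {
  bad <- data.frame(kind = character(), message = character())
  note <- function(kind, msg)
    rbind(bad, data.frame(kind = kind, message = msg))
  e <- g$edges
  if (nrow(e) > 0L) {
    oob <- e$from < 1L | e$from > g$n | e$to < 1L | e$to > g$n
    if (any(oob))
      bad <- note("range", sprintf("edge %d (%d->%d) has vertex out of 1..%d",
                                   which(oob)[1], e$from[which(oob)[1]],
                                   e$to[which(oob)[1]], g$n))
    if (any(e$weight <= 0))
      bad <- note("weight", sprintf("edge %d has nonpositive weight %g",
                                    which(e$weight <= 0)[1],
                                    e$weight[which(e$weight <= 0)[1]]))
  }
  if (nrow(bad) > 0L) return(bad)   # degree/topo checks need sane indices
  ord <- try(topological_order(g), silent = TRUE)
  if (inherits(ord, "try-error")) {
    bad <- note("cycle", "graph contains a directed cycle")
    return(bad)
  }
  deg <- vertex_degrees(g)
  src <- which(deg$indeg == 0L)
  snk <- which(deg$outdeg == 0L)
  if (length(src) != 1L)
    bad <- note("source", sprintf("%d vertices with indegree 0 (%s)",
                                  length(src),
                                  paste(utils::head(src, 5), collapse = ",")))
  if (length(snk) != 1L)
    bad <- note("sink", sprintf("%d vertices with outdegree 0 (%s)",
                                length(snk),
                                paste(utils::head(snk, 5), collapse = ",")))
  io <- in_out_flow(g)
  internal <- setdiff(seq_len(g$n), c(src, snk))
  res <- abs(io$fin[internal] - io$fout[internal])
  lim <- if (g$integer_mode) 0 else tol * pmax(io$fin[internal], 1)
  viol <- which(res > lim)
  for (v in internal[viol])
    bad <- note("conservation",
                sprintf("vertex %d: fin=%g, fout=%g", v, io$fin[v], io$fout[v]))
  bad
}

#' Topological order of the vertices
#'
#' Kahn's algorithm with the frontier kept as a sorted set, so ties are
#' always broken by ascending vertex label and the order is deterministic.
#'
#' @param g A `flow_graph`.
#' @return An integer vector of length `n`; every edge goes forward in it.
#'   Errors on cyclic input, naming one edge on a cycle.
#' @export
topological_order <- function(g) {
  n <- g$n
  indeg <- tabulate(g$edges$to, nbins = n)
  out_edges <- split(seq_len(nrow(g$edges)), factor(g$edges$from, levels = seq_len(n)))
  frontier <- which(indeg == 0L)
  ord <- integer(0)
  while (length(frontier) > 0L) {
    v <- min(frontier)
    frontier <- frontier[frontier != v]
    ord <- c(ord, v)
    for (eid in out_edges[[v]]) {
      w <- g$edges$to[eid]
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) frontier <- c(frontier, w)
    }
  }
  if (length(ord) < n) {
    left <- setdiff(seq_len(n), ord)
    eid <- which(g$edges$from %in% left & g$edges$to %in% left)[1]
    stop(sprintf("graph is cyclic: edge %d (%d->%d) lies on a cycle",
                 eid, g$edges$from[eid], g$edges$to[eid]))
  }
  ord
}

#' Per-vertex in- and out-flow
#'
#' Single pass over the edge list. For a valid flow graph,
#' `fin(v) == fout(v)` at every internal vertex, `fout(s) == fin(t)` is the
#' total flow value, and `fin(s) == fout(t) == 0`.
#'
#' @param g A `flow_graph`.
#' @return A list with numeric vectors `fin` and `fout` of length `n`.
#' @export
in_out_flow <- function(g) {
  list(fin = as.numeric(rowsum_by(g$edges$weight, g$edges$to, g$n)),
       fout = as.numeric(rowsum_by(g$edges$weight, g$edges$from, g$n)))
}

rowsum_by <- function(x, f, n) {
  out <- numeric(n)
  if (length(x) > 0L) {
    s <- rowsum(x, group = f)
    out[as.integer(rownames(s))] <- s[, 1]
  }
  out
}

#' Vertex sequence of an edge-id path
#'
#' @param g A `flow_graph`.
#' @param edge_ids Nonempty integer vector of edge ids forming a contiguous
#'   directed path (the head of each edge is the tail of the next).
#' @return Integer vector of `length(edge_ids) + 1` vertices.
#' @export
path_vertices <- function(g, edge_ids) {
  edge_ids <- as.integer(edge_ids)
  if (length(edge_ids) == 0L) stop("empty path")
  if (any(edge_ids < 1L | edge_ids > nrow(g$edges)))
    stop("edge id out of range")
  from <- g$edges$from[edge_ids]
  to <- g$edges$to[edge_ids]
  k <- length(edge_ids)
  if (k > 1L && any(to[-k] != from[-1L]))
    stop("edge ids do not form a contiguous path")
  c(from[1L], to)
}

# Edge ids of a vertex-sequence path; errors if some step has no edge or is
# ambiguous (parallel edges).
edges_of_vertex_path <- function(g, vertices) {
  if (length(vertices) < 2L) stop("vertex path needs at least 2 vertices")
  key <- paste(g$edges$from, g$edges$to)
  ids <- integer(length(vertices) - 1L)
  for (i in seq_along(ids)) {
    hit <- which(key == paste(vertices[i], vertices[i + 1L]))
    if (length(hit) == 0L)
      stop(sprintf("no edge %d->%d in graph", vertices[i], vertices[i + 1L]))
    if (length(hit) > 1L)
      stop(sprintf("ambiguous step %d->%d: parallel edges %s",
                   vertices[i], vertices[i + 1L], paste(hit, collapse = ",")))
    ids[i] <- hit
  }
  ids
}
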