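#' Maximal unitigs of a flow graph
#'
#' A unitig is a path whose internal vertices have indegree and outdegree
#' exactly 1 (degrees count parallel edges). Maximal unitigs partition the
#' edge set: an edge starts a maximal unitig iff its tail is not a
#' unit-in/unit-out vertex, and the unitig follows unique out-edges through
#' unit/unit vertices. Unitigs are trivially safe: every source-to-sink
#' path through any of their edges traverses them entirely.
#'
#' @param g A valid `flow_graph`.
#' @return List of integer edge-id vectors; every edge belongs to exactly
#'   one.
#' @export
unitigs <- function(g) {
  deg <- vertex_degrees(g)
  through <- deg$indeg == 1L & deg$outdeg == 1L
  out_edge <- rep(NA_integer_, g$n)
  out_edge[g$edges$from[through[g$edges$from]]] <-
    which(through[g$edges$from])
  res <- list()
  for (e0 in which(!through[g$edges$from])) {
    p <- e0
    v <- g$edges$to[e0]
    while (through[v]) {
      nxt <- out_edge[v]
      p <- c(p, nxt)
      v <- g$edges$to[nxt]
    }
    res[[length(res) + 1L]] <- p
  }
  res
}

#' Extended unitigs
#'
#' Every edge (each single-edge unitig, which subsumes seeding from the
#' maximal unitigs) is extended to the left for as long as its first vertex
#' has indegree exactly 1 (prepending that unique in-edge) and to the right
#' for as long as its last vertex has outdegree exactly 1, then the results
#' are deduplicated with [deduplicate_subpaths()]. The extension is purely
#' degree-based — flow values play no role — yet every extended unitig has
#' strictly positive excess flow and is therefore safe.
#'
#' @param g A valid `flow_graph`.
#' @return Deduplicated list of integer edge-id vectors.
#' @export
extended_unitigs <- function(g) {
  deg <- vertex_degrees(g)
  in_edge <- rep(NA_integer_, g$n)
  one_in <- deg$indeg == 1L
  in_edge[g$edges$to[one_in[g$edges$to]]] <- which(one_in[g$edges$to])
  out_edge <- rep(NA_integer_, g$n)
  one_out <- deg$outdeg == 1L
  out_edge[g$edges$from[one_out[g$edges$from]]] <- which(one_out[g$edges$from])
  res <- vector("list", nrow(g$edges))
  for (e0 in seq_len(nrow(g$edges))) {
    p <- e0
    v <- g$edges$from[e0]
    while (deg$indeg[v] == 1L) {
      eid <- in_edge[v]
      p <- c(eid, p)
      v <- g$edges$from[eid]
    }
    v <- g$edges$to[p[length(p)]]
    while (deg$outdeg[v] == 1L) {
      eid <- out_edge[v]
      p <- c(p, eid)
      v <- g$edges$to[eid]
    }
    res[[e0]] <- p
  }
  deduplicate_subpaths(res)
}

#' Funnel test
#'
#' A DAG is a funnel when every source-to-sink path carries a private edge
#' used by no other source-to-sink path; equivalently, no merge vertex
#' (indegree >= 2) reaches a fork vertex (outdegree >= 2) by a directed
#' path, possibly of length zero (a single vertex that both merges and
#' forks already breaks the property). Funnels have a unique flow
#' decomposition, and their extended unitigs are exactly all
#' source-to-sink paths. Implemented as an O(n + m) sweep in topological
#' order marking descendants of merge vertices.
#'
#' @param g A valid `flow_graph` (weights are irrelevant).
#' @return `TRUE` iff the graph is a funnel.
#' @export
is_funnel <- function(g) {
  deg <- vertex_degrees(g)
  tainted <- logical(g$n)    # merge vertex, or reachable from one
  in_edges <- split(seq_len(nrow(g$edges)),
                    factor(g$edges$to, levels = seq_len(g$n)))
  for (v in topological_order(g)) {
    if (deg$indeg[v] >= 2L || any(tainted[g$edges$from[in_edges[[v]]]]))
      tainted[v] <- TRUE
    if (tainted[v] && deg$outdeg[v] >= 2L) return(FALSE)
  }
  TRUE
}
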