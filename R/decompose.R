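new_decomposition <- function(paths, provenance) {
  structure(list(paths = paths, provenance = provenance),
            class = "flow_decomposition")
}

#' @export
print.flow_decomposition <- function(x, ...) {
  cat(sprintf("<flow_decomposition (%s): %d paths, total size %d>\n",
              x$provenance, length(x$paths), sum(lengths(lapply(x$paths, `[[`, "edge_ids")))))
  invisible(x)
}

# first positive-residual in/out edge of v, smallest edge id
first_residual_edge <- function(g, res, v, direction) {
  ids <- if (direction == "in") which(g$edges$to == v & res > 0)
         else which(g$edges$from == v & res > 0)
  if (length(ids) == 0L)
    stop(sprintf("conservation violated at vertex %d during peeling", v))
  min(ids)
}

#' Simple flow decomposition by minimum-edge peeling
#'
#' Repeatedly selects the edge with the globally smallest positive residual
#' flow, extends it to the source and sink through positive-residual edges
#' (ties broken by smallest edge id), peels the resulting path at the
#' selected edge's residual weight, and subtracts. Because the selected
#' edge is a global minimum, the peel zeroes at least one edge per
#' iteration, so at most `m` paths are produced and the residual ends at
#' zero. This is the decomposition used to seed the safe-path enumeration.
#'
#' @param g A valid `flow_graph`.
#' @return A `flow_decomposition`: list with `paths` (each
#'   `list(edge_ids, weight)`) and `provenance`.
#' @export
simple_flow_decomposition <- function(g) {
  s <- flow_source(g); t <- flow_sink(g)
  res <- g$edges$weight
  eps <- if (g$integer_mode) 0 else 1e-9 * max(1, sum(res))
  paths <- list()
  while (any(res > eps)) {
    alive <- which(res > eps)
    e0 <- alive[which.min(res[alive])]   # ties: which.min takes first = smallest id
    w <- res[e0]
    left <- integer(0)
    v <- g$edges$from[e0]
    while (v != s) {
      eid <- first_residual_edge(g, res, v, "in")
      left <- c(eid, left)
      v <- g$edges$from[eid]
    }
    right <- integer(0)
    v <- g$edges$to[e0]
    while (v != t) {
      eid <- first_residual_edge(g, res, v, "out")
      right <- c(right, eid)
      v <- g$edges$to[eid]
    }
    p <- c(left, e0, right)
    res[p] <- res[p] - w
    paths[[length(paths) + 1L]] <- list(edge_ids = p, weight = w)
  }
  new_decomposition(paths, "simple")
}

#' Widest (maximum-bottleneck) source-to-sink path
#'
#' Dynamic programming over the topological order: the width of a vertex is
#' the best over its positive-residual in-edges of `min(width(tail),
#' residual(edge))`. Ties are broken by the smallest predecessor edge id,
#' so the result is deterministic.
#'
#' @param g A `flow_graph`.
#' @param residual Residual edge weights (defaults to the graph's weights).
#' @return `list(edge_ids, weight)` where `weight` is the bottleneck.
#'   Errors if no positive-residual s-t path exists.
#' @export
widest_path <- function(g, residual = g$edges$weight) {
  s <- flow_source(g); t <- flow_sink(g)
  eps <- if (g$integer_mode) 0 else 1e-9 * max(1, sum(g$edges$weight))
  width <- rep(-Inf, g$n)
  width[s] <- Inf
  pred <- rep(NA_integer_, g$n)
  in_edges <- split(seq_len(nrow(g$edges)),
                    factor(g$edges$to, levels = seq_len(g$n)))
  for (v in topological_order(g)) {
    for (eid in in_edges[[v]]) {      # ascending edge id
      if (residual[eid] <= eps) next
      cand <- min(width[g$edges$from[eid]], residual[eid])
      if (cand > width[v]) { width[v] <- cand; pred[v] <- eid }
    }
  }
  if (!is.finite(width[t]) || width[t] <= eps)
    stop("no source-to-sink path with positive residual flow")
  p <- integer(0)
  v <- t
  while (v != s) {
    p <- c(pred[v], p)
    v <- g$edges$from[pred[v]]
  }
  list(edge_ids = p, weight = width[t])
}

#' Greedy-width flow decomposition
#'
#' The classical heuristic: repeatedly remove a widest (maximum-bottleneck)
#' s-t path at its bottleneck weight until the residual flow is zero. Each
#' peel zeroes at least one edge (the bottleneck), so at most `m` paths are
#' produced. The widest-path dynamic program is re-run after each peel.
#'
#' @param g A valid `flow_graph`.
#' @return A `flow_decomposition`.
#' @export
greedy_width_decomposition <- function(g) {
  res <- g$edges$weight
  eps <- if (g$integer_mode) 0 else 1e-9 * max(1, sum(res))
  paths <- list()
  while (any(res > eps)) {
    wp <- widest_path(g, res)
    res[wp$edge_ids] <- res[wp$edge_ids] - wp$weight
    paths[[length(paths) + 1L]] <- wp
  }
  new_decomposition(paths, "greedy-width")
}

#' Verify a flow decomposition
#'
#' Checks that every path runs from the source to the sink along contiguous
#' edges with positive weight, and that on every edge the path weights sum
#' exactly (integer mode) or within tolerance to the edge's flow.
#'
#' @param g A `flow_graph`.
#' @param d A `flow_decomposition`.
#' @return `TRUE` or `FALSE`, with a `diagnostics` attribute (character
#'   vector) naming the first offending paths/edges when `FALSE`.
#' @export
verify_decomposition <- function(g, d) {
  diag <- character(0)
  s <- flow_source(g); t <- flow_sink(g)
  cover <- numeric(nrow(g$edges))
  for (i in seq_along(d$paths)) {
    p <- d$paths[[i]]
    verts <- try(path_vertices(g, p$edge_ids), silent = TRUE)
    if (inherits(verts, "try-error")) {
      diag <- c(diag, sprintf("path %d is not a contiguous path", i))
      next
    }
    if (verts[1L] != s || verts[length(verts)] != t)
      diag <- c(diag, sprintf("path %d does not run from source to sink", i))
    if (p$weight <= 0)
      diag <- c(diag, sprintf("path %d has nonpositive weight %g", i, p$weight))
    cover[p$edge_ids] <- cover[p$edge_ids] + p$weight
  }
  eps <- if (g$integer_mode) 0 else 1e-9 * max(1, sum(g$edges$weight))
  off <- which(abs(cover - g$edges$weight) > eps)
  if (length(off) > 0L)
    diag <- c(diag, sprintf("edge %d: flow %g but path weights sum to %g",
                            off[1], g$edges$weight[off[1]], cover[off[1]]))
  structure(length(diag) == 0L, diagnostics = diag)
}
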