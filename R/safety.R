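#' Preprocess a flow graph for constant-time safety arithmetic
#'
#' Computes the per-vertex in-/out-flow table once (a single pass over the
#' edges), after which the excess flow of any path can be evaluated in time
#' linear in its length, and updated in constant time per single-edge
#' extension or contraction via [extend_delta()].
#'
#' @param g A `flow_graph`.
#' @return An object of class `safety_index`: list with `graph`, `fin`,
#'   `fout`, and the comparison tolerance `tol` (0 in integer mode).
#' @export
safety_index <- function(g) {
  io <- in_out_flow(g)
  structure(list(graph = g, fin = io$fin, fout = io$fout,
                 tol = if (g$integer_mode) 0 else
                   1e-9 * max(1, sum(g$edges$weight))),
            class = "safety_index")
}

as_safety_index <- function(x) {
  if (inherits(x, "safety_index")) x
  else if (inherits(x, "flow_graph")) safety_index(x)
  else stop("expected a flow_graph or safety_index")
}

#' Excess flow of a path
#'
#' The excess flow of a path is the amount of flow that must traverse the
#' path in its entirety in every flow decomposition. In the *diverging*
#' formulation it is the weight of the first edge minus the flow that can
#' leak out at internal vertices (for each internal vertex `u`, the
#' out-flow of `u` not carried by the path's own edge leaving `u`); the
#' *converging* formulation is the mirror image using the last edge and
#' flow entering at internal vertices. Conservation of flow makes the two
#' formulations identical; both are computed and asserted equal (exactly in
#' integer mode). A single-edge path has no internal vertices, so its
#' excess is the edge weight itself.
#'
#' @param x A `flow_graph` or a [safety_index()].
#' @param edge_ids Nonempty contiguous edge-id path.
#' @return The excess flow (may be negative or zero for unsafe paths).
#' @examples
#' g <- flow_graph(5, data.frame(from = c(1, 2, 2, 3, 4),
#'                               to   = c(2, 3, 4, 5, 5),
#'                               weight = c(5, 3, 2, 3, 2)))
#' excess_flow(g, c(1, 2))  # 5 - (5 - 3) = 3
#' @export
excess_flow <- function(x, edge_ids) {
  idx <- as_safety_index(x)
  g <- idx$graph
  verts <- path_vertices(g, edge_ids)      # errors on empty/non-contiguous
  w <- g$edges$weight[edge_ids]
  k <- length(edge_ids)
  if (k == 1L) return(w[1L])
  internal <- verts[2:k]
  # diverging: leak at internal u = fout(u) - weight of path edge leaving u
  div <- w[1L] - sum(idx$fout[internal] - w[2:k])
  # converging: leak at internal u = fin(u) - weight of path edge entering u
  con <- w[k] - sum(idx$fin[internal] - w[1:(k - 1L)])
  if (abs(div - con) > idx$tol)
    stop(sprintf("diverging (%g) and converging (%g) excess disagree: graph violates conservation",
                 div, con))
  div
}

#' Verify w-safety of a path
#'
#' A path is *w-safe* if in every flow decomposition it is a subpath of
#' decomposition paths of total weight at least `w`; this holds exactly
#' when its excess flow is at least `w`. A path is *safe* if it is w-safe
#' for some `w > 0`, i.e. when its excess flow is strictly positive.
#'
#' @inheritParams excess_flow
#' @param w Positive flow amount.
#' @return `TRUE` iff the path is w-safe.
#' @export
is_w_safe <- function(x, edge_ids, w) {
  if (!is.numeric(w) || length(w) != 1L || w <= 0)
    stop("w-safety is defined only for w > 0")
  idx <- as_safety_index(x)
  excess_flow(idx, edge_ids) >= w - idx$tol
}

#' Excess-flow reduction from a single-edge extension
#'
#' Appending edge `(u, v)` to the *end* of a path ending at `u` reduces its
#' excess flow by `fout(u) - f(u, v)`; prepending it to the *start* of a
#' path beginning at `v` reduces it by `fin(v) - f(u, v)`. Both amounts are
#' nonnegative, so excess flow never increases under extension.
#'
#' @param x A `flow_graph` or `safety_index`.
#' @param edge_id Edge to add.
#' @param side `"start"` or `"end"`.
#' @return The nonnegative reduction in excess flow.
#' @export
extend_delta <- function(x, edge_id, side = c("start", "end")) {
  side <- match.arg(side)
  idx <- as_safety_index(x)
  g <- idx$graph
  edge_id <- as.integer(edge_id)
  if (edge_id < 1L || edge_id > nrow(g$edges)) stop("edge id out of range")
  w <- g$edges$weight[edge_id]
  if (side == "start") idx$fin[g$edges$to[edge_id]] - w
  else idx$fout[g$edges$from[edge_id]] - w
}
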