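# Shared fixtures. G1/G2/G3 are small hand-checkable flow graphs used
# across the suite (vertices 1-based; comments give the 0-based labels the
# file format would use).

# diamond funnel: edges (0,1,1),(1,3,1),(0,2,2),(2,3,2)
make_g1 <- function() {
  flow_graph(4, data.frame(from = c(1, 2, 1, 3), to = c(2, 4, 3, 4),
                           weight = c(1, 1, 2, 2)), name = "g1")
}

# fork after a heavy edge: (0,1,5),(1,2,3),(1,3,2),(2,4,3),(3,4,2)
make_g2 <- function() {
  flow_graph(5, data.frame(from = c(1, 2, 2, 3, 4), to = c(2, 3, 4, 5, 5),
                           weight = c(5, 3, 2, 3, 2)), name = "g2")
}

# double diamond: (0,1,1),(0,2,2),(1,3,1),(2,3,2),(3,4,1),(3,5,2),(4,6,1),(5,6,2)
make_g3 <- function() {
  flow_graph(7, data.frame(from = c(1, 1, 2, 3, 4, 4, 5, 6),
                           to = c(2, 3, 4, 4, 5, 6, 7, 7),
                           weight = c(1, 2, 1, 2, 1, 2, 1, 2)), name = "g3")
}

# Random integer flow graph within the brute-force oracle guard: superpose
# a few unit/low-weight random walks on a small random DAG skeleton.
random_guarded_graph <- function(n = 6L, n_walks = 3L, max_w = 2L,
                                 max_total = 6L, max_edges = 10L) {
  repeat {
    out <- vector("list", n)
    for (v in seq_len(n - 1L)) {
      succ <- (v + 1L):n
      take <- succ[stats::runif(length(succ)) < 2.2 / length(succ)]
      if (length(take) == 0L) take <- succ[sample.int(length(succ), 1L)]
      out[[v]] <- take
    }
    walk <- function() {
      v <- 1L
      path <- integer(0)
      while (v < n) {
        nxt <- if (length(out[[v]]) == 1L) out[[v]] else sample(out[[v]], 1L)
        path <- c(path, v)
        v <- nxt
      }
      c(path, n)
    }
    k <- sample.int(n_walks, 1L)
    acc <- list()
    total <- 0
    for (i in seq_len(k)) {
      w <- sample.int(max_w, 1L)
      if (total + w > max_total) next
      total <- total + w
      vs <- walk()
      for (j in seq_len(length(vs) - 1L)) {
        key <- paste(vs[j], vs[j + 1L])
        acc[[key]] <- if (is.null(acc[[key]])) w else acc[[key]] + w
      }
    }
    if (length(acc) == 0L || length(acc) > max_edges) next
    uv <- do.call(rbind, strsplit(names(acc), " "))
    used <- sort(unique(as.integer(uv)))
    remap <- integer(n); remap[used] <- seq_along(used)
    edges <- data.frame(from = remap[as.integer(uv[, 1])],
                        to = remap[as.integer(uv[, 2])],
                        weight = unlist(acc))
    edges <- edges[order(edges$from, edges$to), ]
    g <- try(flow_graph(length(used), edges, name = "rnd"), silent = TRUE)
    if (!inherits(g, "try-error")) return(g)
  }
}

# Independent naive excess-flow formulations (straight from the definition,
# no shared code with excess_flow beyond the graph accessors).
excess_div_naive <- function(g, edge_ids) {
  io <- in_out_flow(g)
  vs <- path_vertices(g, edge_ids)
  w <- g$edges$weight[edge_ids]
  k <- length(edge_ids)
  if (k == 1L) return(w[1])
  leak <- 0
  for (j in 2:k) leak <- leak + (io$fout[vs[j]] - w[j])
  w[1] - leak
}

excess_con_naive <- function(g, edge_ids) {
  io <- in_out_flow(g)
  vs <- path_vertices(g, edge_ids)
  w <- g$edges$weight[edge_ids]
  k <- length(edge_ids)
  if (k == 1L) return(w[1])
  leak <- 0
  for (j in 2:k) leak <- leak + (io$fin[vs[j]] - w[j - 1L])
  w[k] - leak
}

# random contiguous path of <= max_len edges, as edge ids
random_path <- function(g, max_len = 6L) {
  e <- sample.int(nrow(g$edges), 1L)
  p <- e
  while (length(p) < max_len) {
    nxt <- which(g$edges$from == g$edges$to[p[length(p)]])
    if (length(nxt) == 0L || stats::runif(1) < 0.25) break
    p <- c(p, if (length(nxt) == 1L) nxt else sample(nxt, 1L))
  }
  p
}

path_key <- function(ids) paste(ids, collapse = ",")

canon_path_set <- function(paths) sort(vapply(paths, path_key, character(1)))

# vertex-sequence canonical set (for comparisons robust to edge ids)
canon_vpath_set <- function(g, paths) {
  sort(vapply(paths, function(p) paste(path_vertices(g, p), collapse = ","),
              character(1)))
}

tmpfile <- function() tempfile(fileext = ".txt")
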