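# Run code under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards so simulation is reproducible without side
# effects.
sample1 <- function(x) if (length(x) == 1L) x else sample(x, 1L)

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Simulation configuration for splice-graph instances
#'
#' Defaults emulate error-free splice graphs built by superimposing
#' weighted transcripts: an ordered exon backbone, transcripts as distinct
#' increasing exon subsequences (each exon skipped independently with
#' probability `skip_prob`), and per-transcript abundances drawn from a
#' lognormal distribution with log-space mean `meanlog = -4` and variance
#' `sdlog^2 = 4`, scaled and integerized as `round(scale * x) + 1` so all
#' downstream flow arithmetic is exact.
#'
#' @param k Number of transcripts (the instance complexity).
#' @param exon_range Inclusive range for the exon-backbone size.
#' @param skip_prob Probability that a transcript skips a given exon.
#' @param meanlog,sdlog Lognormal parameters for raw abundances.
#' @param scale Multiplier applied before integerization.
#' @param integerize If `TRUE` (default) round to positive integers;
#'   otherwise keep raw lognormal weights (float mode).
#' @param length_range Inclusive range for per-exon base lengths.
#' @param seed Optional seed; a fixed seed yields a byte-identical
#'   instance.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(k = 5L, exon_range = c(10L, 30L), skip_prob = 0.3,
                       meanlog = -4, sdlog = 2, scale = 1000,
                       integerize = TRUE, length_range = c(50L, 300L),
                       seed = NULL) {
  stopifnot(k >= 1L, sdlog > 0, skip_prob >= 0, skip_prob < 1,
            length(exon_range) == 2L, exon_range[1] >= 2L)
  structure(list(k = as.integer(k), exon_range = as.integer(exon_range),
                 skip_prob = skip_prob, meanlog = meanlog, sdlog = sdlog,
                 scale = scale, integerize = integerize,
                 length_range = as.integer(length_range), seed = seed),
            class = "sim_config")
}

#' Simulate an error-free splice-graph instance
#'
#' Draws an ordered exon backbone and `k` distinct transcripts (increasing
#' exon subsequences; duplicates are rejected and redrawn), assigns each a
#' lognormal abundance, and superimposes the weighted transcripts into a
#' flow graph with an artificial global source pointing at the first exon
#' of every transcript and an artificial global sink collecting the last
#' exons. The resulting graph satisfies conservation of flow by
#' construction, and the ground truth is always one of its flow
#' decompositions. Exon base lengths are drawn uniformly from
#' `length_range`; the artificial source/sink get length 0.
#'
#' @param cfg A [sim_config()].
#' @return A list of class `splice_instance`: `graph` (a `flow_graph` with
#'   `artificial_st` set), `truth` (list of `list(vertices, weight)` with
#'   source/sink included), `node_lengths`, `k`, and `config`.
#' @examples
#' inst <- simulate_splice_instance(sim_config(k = 4, seed = 1))
#' inst$graph
#' @export
simulate_splice_instance <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    n_exons <- sample1(cfg$exon_range[1]:cfg$exon_range[2])
    if (2^n_exons - 1 < cfg$k)
      stop(sprintf("k = %d exceeds the %g distinct transcripts available on %d exons",
                   cfg$k, 2^n_exons - 1, n_exons))
    transcripts <- list()
    seen <- character(0)
    attempts <- 0L
    while (length(transcripts) < cfg$k) {
      attempts <- attempts + 1L
      if (attempts > 1000L * cfg$k)
        stop("could not draw enough distinct transcripts; lower skip_prob or raise exon_range")
      keep <- which(stats::runif(n_exons) > cfg$skip_prob)
      if (length(keep) == 0L) next
      key <- paste(keep, collapse = ",")
      if (key %in% seen) next
      seen <- c(seen, key)
      transcripts[[length(transcripts) + 1L]] <- keep
    }
    raw <- stats::rlnorm(cfg$k, meanlog = cfg$meanlog, sdlog = cfg$sdlog)
    weights <- if (cfg$integerize) round(cfg$scale * raw) + 1 else cfg$scale * raw
    exon_lengths <- sample(cfg$length_range[1]:cfg$length_range[2],
                           n_exons, replace = TRUE)
    build_superposition(transcripts, weights, exon_lengths, cfg)
  })
}

# Superimpose weighted exon paths into a flow graph with global s/t.
# Unused exons are dropped and the rest renumbered, so the source is unique.
build_superposition <- function(transcripts, weights, exon_lengths, cfg = NULL) {
  used <- sort(unique(unlist(transcripts)))
  remap <- integer(max(used))
  remap[used] <- seq_along(used) + 1L    # exons occupy 2..U+1
  s <- 1L
  t <- length(used) + 2L
  n <- t
  acc <- new.env(parent = emptyenv())
  add_edge <- function(u, v, w) {
    key <- paste(u, v)
    acc[[key]] <- if (is.null(acc[[key]])) w else acc[[key]] + w
  }
  truth <- vector("list", length(transcripts))
  for (i in seq_along(transcripts)) {
    v <- c(s, remap[transcripts[[i]]], t)
    truth[[i]] <- list(vertices = v, weight = weights[i])
    for (j in seq_len(length(v) - 1L)) add_edge(v[j], v[j + 1L], weights[i])
  }
  keys <- ls(acc)
  uv <- do.call(rbind, strsplit(keys, " "))
  edges <- data.frame(from = as.integer(uv[, 1]), to = as.integer(uv[, 2]),
                      weight = vapply(keys, function(k) acc[[k]], numeric(1)))
  edges <- edges[order(edges$from, edges$to), ]
  rownames(edges) <- NULL
  node_lengths <- c(0, exon_lengths[used], 0)
  g <- flow_graph(n, edges, name = sprintf("sim_k%d", length(transcripts)),
                  node_lengths = node_lengths)
  g$artificial_st <- c(s, t)
  structure(list(graph = g, truth = truth, node_lengths = node_lengths,
                 k = length(transcripts), config = cfg),
            class = "splice_instance")
}

#' @export
print.splice_instance <- function(x, ...) {
  cat(sprintf("<splice_instance: k = %d, %d vertices, %d edges, funnel = %s>\n",
              x$k, x$graph$n, nrow(x$graph$edges), is_funnel(x$graph)))
  invisible(x)
}

#' Worst-case family for the enumeration algorithm
#'
#' Four-block ladder: an A-chain `a1..ak`, a layer C fanning out of `ak`, a
#' layer D feeding `b1`, and a B-chain `b1..bk`, with a chosen subset of
#' C-to-D edges each carrying unit flow and all chain weights derived by
#' conservation. Every C-to-D edge then supports its own maximal safe path
#' spanning the whole source-to-sink route, so the concise representation
#' is as large as the decomposition itself (the worst case).
#'
#' @param k Ladder depth (>= 2).
#' @param cd_edges Two-column matrix of (C-index, D-index) pairs in
#'   `1..k`; defaults to the full C x D grid. Unused C/D vertices are
#'   dropped.
#' @return A valid `flow_graph`.
#' @export
worst_case_graph <- function(k, cd_edges = NULL) {
  stopifnot(k >= 2L)
  k <- as.integer(k)
  if (is.null(cd_edges))
    cd_edges <- as.matrix(expand.grid(ci = seq_len(k), dj = seq_len(k)))
  cd_edges <- matrix(as.integer(cd_edges), ncol = 2L)
  if (nrow(cd_edges) == 0L) stop("cd_edges must be nonempty")
  if (any(cd_edges < 1L | cd_edges > k)) stop("cd_edges indices out of 1..k")
  cs <- sort(unique(cd_edges[, 1])); ds <- sort(unique(cd_edges[, 2]))
  FF <- nrow(cd_edges)
  # vertices: a1..ak, used C, used D, b1..bk
  aid <- seq_len(k)
  cid <- k + seq_along(cs)
  did <- k + length(cs) + seq_along(ds)
  bid <- k + length(cs) + length(ds) + seq_len(k)
  n <- bid[k]
  deg_c <- tabulate(match(cd_edges[, 1], cs), nbins = length(cs))
  deg_d <- tabulate(match(cd_edges[, 2], ds), nbins = length(ds))
  edges <- rbind(
    data.frame(from = aid[-k], to = aid[-1L], weight = FF),
    data.frame(from = aid[k], to = cid, weight = deg_c),
    data.frame(from = cid[match(cd_edges[, 1], cs)],
               to = did[match(cd_edges[, 2], ds)], weight = 1),
    data.frame(from = did, to = bid[1L], weight = deg_d),
    data.frame(from = bid[-k], to = bid[-1L], weight = FF))
  flow_graph(n, edges, name = sprintf("worst_k%d", k))
}

#' Best-case family for the enumeration algorithm
#'
#' Same ladder as [worst_case_graph()] with the full C x D grid, except
#' that the links `a(k-1) -> ak` and `b1 -> b2` are split into two parallel
#' edges carrying (near-)equal flow. The parallel split caps the excess of
#' any path crossing it, so the maximal safe paths collapse to: one short
#' path around each C-to-D edge, plus two long paths along each chain (one
#' per parallel edge). The concise representation is then linear in
#' `n + m` while the decomposition size grows superlinearly.
#'
#' @param k Ladder depth (>= 3; even k gives exactly equal parallel flows).
#' @return A valid `flow_graph` containing exactly two parallel-edge pairs.
#' @export
best_case_graph <- function(k) {
  stopifnot(k >= 3L)
  k <- as.integer(k)
  FF <- k * k
  half1 <- ceiling(FF / 2); half2 <- FF - half1
  aid <- seq_len(k); cid <- k + seq_len(k); did <- 2L * k + seq_len(k)
  bid <- 3L * k + seq_len(k)
  chainA <- if (k > 2L)
    data.frame(from = aid[1:(k - 2L)], to = aid[2:(k - 1L)], weight = FF)
  else NULL
  chainB <- if (k > 2L)
    data.frame(from = bid[2:(k - 1L)], to = bid[3:k], weight = FF)
  else NULL
  edges <- rbind(
    chainA,
    data.frame(from = c(aid[k - 1L], aid[k - 1L]), to = c(aid[k], aid[k]),
               weight = c(half1, half2)),
    data.frame(from = aid[k], to = cid, weight = k),
    data.frame(from = rep(cid, each = k), to = rep(did, k), weight = 1),
    data.frame(from = did, to = bid[1L], weight = k),
    data.frame(from = c(bid[1L], bid[1L]), to = c(bid[2L], bid[2L]),
               weight = c(half1, half2)),
    chainB)
  flow_graph(4L * k, edges, name = sprintf("best_k%d", k))
}

#' Random funnel generator
#'
#' Builds a fork phase (a random out-tree hanging from the source) followed
#' by a merge phase (a random in-tree draining into the sink), with cross
#' edges from out-tree leaves onto the merge phase's entry vertices. Merge
#' vertices never reach fork vertices by construction, so the result is
#' always a funnel; weights are obtained by superimposing every
#' source-to-sink path with a random positive integer weight, so the graph
#' is a valid integer flow graph with a unique decomposition.
#'
#' @param n Target vertex count (>= 2; `n = 2` yields a single edge).
#' @param seed Optional seed.
#' @param max_weight Per-path weights are uniform on `1..max_weight`.
#' @return A valid `flow_graph` with `is_funnel(g) == TRUE`.
#' @export
random_funnel <- function(n, seed = NULL, max_weight = 5L) {
  stopifnot(n >= 2L)
  n <- as.integer(n)
  with_seed(seed, {
    if (n == 2L) {
      return(flow_graph(2L, data.frame(from = 1L, to = 2L,
                                       weight = sample.int(max_weight, 1L)),
                        name = "funnel_n2"))
    }
    inner <- n - 2L
    n_fork <- sample1(seq_len(inner))       # vertices in the out-tree (after s)
    n_merge <- inner - n_fork
    s <- 1L
    fork <- if (n_fork > 0L) 1L + seq_len(n_fork) else integer(0)
    merge <- if (n_merge > 0L) 1L + n_fork + seq_len(n_merge) else integer(0)
    t <- n
    from <- integer(0); to <- integer(0)
    for (v in fork) {   # out-tree: parent among earlier fork vertices or s
      parent <- sample1(c(s, fork[fork < v]))
      from <- c(from, parent); to <- c(to, v)
    }
    for (v in rev(merge)) {  # in-tree: child among later merge vertices or t
      child <- sample1(c(t, merge[merge > v]))
      from <- c(from, v); to <- c(to, child)
    }
    out_leaves <- setdiff(c(s, fork), from)      # no out-tree children
    if (length(out_leaves) == 0L) out_leaves <- s
    entries <- setdiff(c(merge, t), to)          # no in-tree parents yet
    if (length(entries) == 0L) entries <- t
    for (v in out_leaves) {
      from <- c(from, v); to <- c(to, sample1(entries))
    }
    uncovered <- setdiff(entries, to)
    for (v in uncovered) {
      from <- c(from, sample1(out_leaves)); to <- c(to, v)
    }
    skeleton <- flow_graph(n, data.frame(from = from, to = to, weight = 1),
                           name = "", validate = FALSE)
    paths <- all_st_paths(skeleton)
    w <- numeric(length(from))
    for (p in paths) {
      pw <- sample.int(max_weight, 1L)
      w[p] <- w[p] + pw
    }
    flow_graph(n, data.frame(from = from, to = to, weight = w),
               name = sprintf("funnel_n%d", n))
  })
}

#' Ground truth as a flow decomposition
#'
#' Converts an instance's weighted transcripts (vertex paths) into a
#' `flow_decomposition` of its graph; by construction of the superposition
#' this always satisfies [verify_decomposition()].
#'
#' @param g The instance's `flow_graph`.
#' @param truth List of `list(vertices, weight)` transcripts.
#' @return A `flow_decomposition` with provenance `"truth"`.
#' @export
truth_decomposition <- function(g, truth) {
  new_decomposition(lapply(truth, function(t)
    list(edge_ids = edges_of_vertex_path(g, t$vertices), weight = t$weight)),
    "truth")
}
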