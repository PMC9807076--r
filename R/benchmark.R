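#' Reported vertex paths for each algorithm on one instance
#'
#' Convenience wrapper running the three evaluated approaches on a splice
#' instance: `safe_complete` (two-pointer enumeration seeded by the simple
#' flow decomposition, expanded to individual paths), `ext_unitigs`
#' (degree-extended unitigs), and `greedy` (greedy-width decomposition
#' paths).
#'
#' @param g A valid `flow_graph`.
#' @return Named list of lists of vertex sequences.
#' @export
algorithm_reports <- function(g) {
  sc <- expand_concise(enumerate_maximal_safe_paths(g))
  eu <- extended_unitigs(g)
  gr <- lapply(greedy_width_decomposition(g)$paths, `[[`, "edge_ids")
  list(safe_complete = lapply(sc, function(p) path_vertices(g, p)),
       ext_unitigs = lapply(eu, function(p) path_vertices(g, p)),
       greedy = lapply(gr, function(p) path_vertices(g, p)))
}

#' Simulate a dataset of non-trivial splice-graph instances
#'
#' Draws instance complexities `k` uniformly from `k_range` and simulates
#' until `n_graphs` instances are collected. Funnel instances have a unique
#' flow decomposition, on which every algorithm scores perfectly; they are
#' filtered out by default so metrics are not diluted, and the funnel
#' fraction encountered is recorded.
#'
#' @param n_graphs Number of instances to keep.
#' @param k_range Inclusive complexity range.
#' @param seed Seed for the whole dataset (per-instance seeds are derived).
#' @param include_funnels Keep funnel instances instead of filtering.
#' @param base_cfg A [sim_config()] supplying all non-`k`, non-`seed`
#'   parameters.
#' @return List of `splice_instance` objects, with attributes
#'   `funnel_fraction` and `n_generated`.
#' @export
simulate_dataset <- function(n_graphs = 200L, k_range = c(2L, 35L),
                             seed = 1L, include_funnels = FALSE,
                             base_cfg = sim_config()) {
  instances <- vector("list", n_graphs)
  kept <- 0L
  generated <- 0L
  funnels <- 0L
  with_seed(seed, {
    while (kept < n_graphs) {
      generated <- generated + 1L
      if (generated > 100L * n_graphs)
        stop("too many funnel instances; widen k_range or adjust the generator")
      cfg <- base_cfg
      cfg$k <- sample1(k_range[1]:k_range[2])
      cfg$seed <- sample.int(.Machine$integer.max - 1L, 1L)
      inst <- simulate_splice_instance(cfg)
      if (is_funnel(inst$graph)) {
        funnels <- funnels + 1L
        if (!include_funnels) next
      }
      kept <- kept + 1L
      inst$graph$name <- sprintf("%s_g%03d", inst$graph$name, kept)
      instances[[kept]] <- inst
    }
  })
  attr(instances, "funnel_fraction") <- funnels / generated
  attr(instances, "n_generated") <- generated
  instances
}

#' End-to-end benchmark: simulate, run all algorithms, evaluate
#'
#' For each instance computes the safe-and-complete paths, the extended
#' unitigs and the greedy-width decomposition, evaluates all three with
#' weighted precision, maximum relative coverage and F-score, and
#' aggregates the per-graph values overall and within the complexity
#' strata `k <= k_split` / `k > k_split`. With the same seed and
#' configuration the per-graph table and summary are reproduced exactly.
#'
#' @param n_graphs,k_range,seed,include_funnels,base_cfg Passed to
#'   [simulate_dataset()]; alternatively supply `instances` directly.
#' @param instances Optional pre-simulated list of `splice_instance`s.
#' @param units Metric units to compute (`"node"`, `"base"` or both).
#' @param k_split Stratum boundary for aggregation.
#' @param out_dir If non-`NULL`, write `per_graph.csv`, `summary.csv` and
#'   `run.json` (configuration + funnel fraction) there.
#' @return List with `per_graph` (data frame), `summary` (data frame), and
#'   `funnel_fraction`.
#' @export
run_benchmark <- function(n_graphs = 200L, k_range = c(2L, 35L), seed = 1L,
                          include_funnels = FALSE, base_cfg = sim_config(),
                          instances = NULL, units = "node", k_split = 10,
                          out_dir = NULL) {
  if (is.null(instances))
    instances <- simulate_dataset(n_graphs, k_range, seed, include_funnels,
                                  base_cfg)
  rows <- list()
  for (inst in instances) {
    reports <- algorithm_reports(inst$graph)
    for (alg in names(reports)) for (u in units) {
      rows[[length(rows) + 1L]] <-
        evaluate_instance(inst, reports[[alg]], unit = u, algorithm = alg)
    }
  }
  per_graph <- do.call(rbind, rows)
  summary <- aggregate_metrics(per_graph, k_split = k_split)
  res <- list(per_graph = per_graph, summary = summary,
              funnel_fraction = attr(instances, "funnel_fraction"))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(per_graph, file.path(out_dir, "per_graph.csv"),
                     row.names = FALSE)
    utils::write.csv(summary, file.path(out_dir, "summary.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(n_graphs = length(instances), k_range = k_range, seed = seed,
           include_funnels = include_funnels, units = units,
           k_split = k_split, funnel_fraction = res$funnel_fraction),
      file.path(out_dir, "run.json"), auto_unbox = TRUE, digits = NA)
  }
  res
}
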