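test_that("subpath test requires contiguity", {
  expect_true(is_subpath(c(1, 2), c(0, 1, 2, 3)))
  expect_false(is_subpath(c(1, 3), c(0, 1, 2, 3)))
  expect_true(is_subpath(c(0, 1, 2, 3), c(0, 1, 2, 3)))
  expect_true(is_subpath(2, c(0, 1, 2, 3)))
  expect_false(is_subpath(c(1, 2, 12), c(1, 2, 1, 2)))  # no token bleeding
})

# canonical worked example: truth s-1-2-3-t, reported (1,2) and (1,3);
# vertices relabelled 1-based with s=1, t=5 artificial
worked_truth <- list(c(1L, 2L, 3L, 4L, 5L))
worked_reported <- list(c(2L, 3L), c(2L, 4L))

test_that("weighted precision matches the worked example in both units", {
  expect_equal(weighted_precision(worked_reported, worked_truth,
                                  artificial = c(1L, 5L)), 0.5)
  # base lengths 10, 10, 1 for the three exons
  nl <- c(0, 10, 10, 1, 0)
  expect_equal(weighted_precision(worked_reported, worked_truth, unit = "base",
                                  node_lengths = nl, artificial = c(1L, 5L)),
               20 / 31)
  # everything a subpath of a transcript
  expect_equal(weighted_precision(list(c(2L, 3L), c(3L, 4L)), worked_truth,
                                  artificial = c(1L, 5L)), 1)
  # vacuous report
  expect_equal(weighted_precision(list(), worked_truth), 1)
})

test_that("maximum relative coverage takes the longest single segment", {
  # truth s-1-2-3-4-t; reported (2,3) covers 2 of 4 nodes
  truth <- list(c(1L, 2L, 3L, 4L, 5L, 6L))
  expect_equal(max_relative_coverage(list(c(3L, 4L)), truth,
                                     artificial = c(1L, 6L)), 0.5)
  # full transcript reported
  expect_equal(max_relative_coverage(list(c(2L, 3L, 4L, 5L)), truth,
                                     artificial = c(1L, 6L)), 1)
  # two segments never merge: (1,2) and (3,4) still give 2/4
  expect_equal(max_relative_coverage(list(c(2L, 3L), c(4L, 5L)), truth,
                                     artificial = c(1L, 6L)), 0.5)
  # a reported path only partially inside the transcript counts its
  # longest inside stretch
  expect_equal(max_relative_coverage(list(c(9L, 2L, 3L, 9L)), truth,
                                     artificial = c(1L, 6L)), 0.5)
  # averaged over transcripts
  t2 <- list(c(1L, 2L, 3L, 4L, 5L, 6L), c(1L, 2L, 4L, 6L))
  expect_equal(max_relative_coverage(list(c(2L, 3L)), t2,
                                     artificial = c(1L, 6L)),
               mean(c(0.5, 0.5)))
})

test_that("coverage in base units maximizes base length, not node count", {
  truth <- list(c(1L, 2L, 3L, 4L, 5L))
  nl <- c(0, 100, 1, 1, 0)
  # (2): 100 bases beats (3,4): 2 bases despite fewer nodes
  expect_equal(max_relative_coverage(list(c(2L), c(3L, 4L)), truth,
                                     unit = "base", node_lengths = nl,
                                     artificial = c(1L, 5L)),
               100 / 102)
})

test_that("f-score is the harmonic mean with the degenerate-zero rule", {
  expect_equal(f_score(1, 1), 1)
  expect_equal(f_score(0.5, 1), 2 / 3)
  expect_equal(f_score(0, 0.7), 0)
  expect_equal(f_score(0, 0), 0)
  for (p in c(0.2, 0.5, 0.9)) for (cv in c(0.1, 0.6, 1)) {
    fs <- f_score(p, cv)
    expect_gte(fs, 0); expect_lte(fs, 1)
    expect_lte(fs, 2 * min(p, cv) / (1 + min(p, cv) / max(p, cv)) + 1e-12)
  }
})

test_that("evaluate_instance strips artificial vertices and fills the record", {
  inst <- simulate_splice_instance(sim_config(k = 3, seed = 5))
  truth_paths <- lapply(inst$truth, `[[`, "vertices")
  r <- evaluate_instance(inst, truth_paths, algorithm = "truth")
  expect_equal(r$precision, 1)
  expect_equal(r$coverage, 1)
  expect_equal(r$fscore, 1)
  expect_equal(r$k, 3L)

  r0 <- evaluate_instance(inst, list())
  expect_equal(r0$precision, 1)   # vacuous
  expect_equal(r0$coverage, 0)
  expect_equal(r0$fscore, 0)
})

test_that("metrics reject parallel-edge graphs and unknown vertices", {
  gp <- flow_graph(2, data.frame(from = c(1, 1), to = c(2, 2),
                                 weight = c(1, 1)))
  inst <- list(graph = gp, truth = list(c(1L, 2L)))
  expect_error(evaluate_instance(inst, list(c(1L, 2L))), "parallel")
  inst2 <- simulate_splice_instance(sim_config(k = 2, seed = 9))
  expect_error(
    evaluate_instance(inst2, list(c(1L, inst2$graph$n + 5L))), "unknown vertex")
})

test_that("coverage is monotone in the reported set", {
  set.seed(73)
  inst <- simulate_splice_instance(sim_config(k = 6, seed = 81))
  g <- inst$graph
  reports <- algorithm_reports(g)
  truth <- lapply(inst$truth, `[[`, "vertices")
  art <- g$artificial_st
  base <- reports$ext_unitigs
  cv <- max_relative_coverage(base, truth, artificial = art)
  for (extra in reports$safe_complete[1:3]) {
    cv2 <- max_relative_coverage(c(base, list(extra)), truth, artificial = art)
    expect_gte(cv2, cv)
  }
})

test_that("aggregation averages per stratum and keeps the harmonic identity", {
  rows <- rbind(
    data.frame(name = "a", k = 3, algorithm = "x", unit = "node",
               precision = 1, coverage = 0.5, fscore = f_score(1, 0.5)),
    data.frame(name = "b", k = 20, algorithm = "x", unit = "node",
               precision = 0.8, coverage = 1, fscore = f_score(0.8, 1)))
  agg <- aggregate_metrics(rows)
  expect_setequal(agg$stratum, c("all", "simple", "complex"))
  expect_equal(agg$precision[agg$stratum == "all"], 0.9)
  expect_equal(agg$n_graphs[agg$stratum == "simple"], 1L)
  expect_equal(agg$coverage[agg$stratum == "complex"], 1)
})
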