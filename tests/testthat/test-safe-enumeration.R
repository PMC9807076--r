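# brute-force reference for the two-pointer scan: classify every window of
# a host path directly from recomputed excess values
host_windows_naive <- function(g, host) {
  L <- length(host)
  safe <- function(a, b) excess_flow(g, host[a:b]) > 0
  out <- NULL
  for (a in seq_len(L)) for (b in a:L) {
    if (safe(a, b) &&
        (a == 1L || !safe(a - 1L, b)) &&
        (b == L || !safe(a, b + 1L)))
      out <- rbind(out, data.frame(left = a, right = b))
  }
  out
}

test_that("two-pointer windows equal the brute-force host-maximal windows", {
  g2 <- make_g2()
  w <- maximal_safe_paths_on_path(g2, c(1, 2, 4))
  expect_equal(w$left, 1L)
  expect_equal(w$right, 3L)
  expect_equal(w$excess, 3)

  set.seed(41)
  for (i in 1:20) {
    g <- random_guarded_graph()
    for (host in all_st_paths(g)) {
      got <- maximal_safe_paths_on_path(g, host)
      want <- host_windows_naive(g, host)
      expect_equal(got[c("left", "right")], want)
      for (j in seq_len(nrow(got)))
        expect_equal(got$excess[j],
                     excess_flow(g, host[got$left[j]:got$right[j]]))
      expect_true(all(got$excess > 0))
    }
  }
})

test_that("a chain host yields a single window covering the whole host", {
  chain <- flow_graph(4, data.frame(from = 1:3, to = 2:4, weight = 4))
  w <- maximal_safe_paths_on_path(chain, 1:3)
  expect_equal(w, data.frame(left = 1L, right = 3L, excess = 4))
})

test_that("substring deduplication keeps first occurrences only", {
  expect_equal(deduplicate_subpaths(list(c(1L, 2L), c(1L, 2L))),
               list(c(1L, 2L)))
  expect_equal(deduplicate_subpaths(list(2L, c(1L, 2L, 3L))),
               list(c(1L, 2L, 3L)))
  # overlap is not containment
  expect_equal(deduplicate_subpaths(list(c(1L, 2L), c(2L, 3L))),
               list(c(1L, 2L), c(2L, 3L)))
  # interior substring removed, not only prefixes/suffixes
  expect_equal(deduplicate_subpaths(list(c(2L, 3L), c(1L, 2L, 3L, 4L))),
               list(c(1L, 2L, 3L, 4L)))
  # id 12 must not swallow ids 1,2
  expect_equal(deduplicate_subpaths(list(c(1L, 2L), c(12L, 13L))),
               list(c(1L, 2L), c(12L, 13L)))
})

test_that("expansion materializes windows and handles empty input", {
  cp <- structure(list(entries = list(list(
    host = 1L, edge_ids = c(5L, 6L, 7L, 8L),
    windows = data.frame(left = c(1L, 2L), right = c(3L, 4L),
                         excess = c(1, 1))))), class = "concise_paths")
  expect_equal(expand_concise(cp), list(c(5L, 6L, 7L), c(6L, 7L, 8L)))
  expect_equal(concise_size(cp), 4L)
  empty <- structure(list(entries = list()), class = "concise_paths")
  expect_equal(expand_concise(empty), list())
})

test_that("funnel enumeration reports exactly the s-t paths", {
  g1 <- make_g1()
  got <- expand_concise(enumerate_maximal_safe_paths(g1))
  expect_setequal(canon_path_set(got), canon_path_set(all_st_paths(g1)))
  chain <- flow_graph(3, data.frame(from = c(1, 2), to = c(2, 3), weight = 7))
  expect_equal(expand_concise(enumerate_maximal_safe_paths(chain)),
               list(c(1L, 2L)))
})

test_that("enumeration equals the oracle-derived maximal safe set", {
  g3 <- make_g3()
  expect_setequal(
    canon_path_set(expand_concise(enumerate_maximal_safe_paths(g3))),
    canon_path_set(oracle_maximal_safe_paths(g3)))

  set.seed(43)
  for (i in 1:15) {
    g <- random_guarded_graph()
    expect_setequal(
      canon_path_set(expand_concise(enumerate_maximal_safe_paths(g))),
      canon_path_set(oracle_maximal_safe_paths(g)))
  }
})

test_that("expanded paths are safe and globally inextensible", {
  set.seed(47)
  for (i in 1:10) {
    inst <- simulate_splice_instance(sim_config(k = sample(2:8, 1),
                                                exon_range = c(5L, 10L),
                                                seed = sample.int(1e6, 1)))
    g <- inst$graph
    idx <- safety_index(g)
    for (p in expand_concise(enumerate_maximal_safe_paths(g))) {
      ex <- excess_flow(idx, p)
      expect_gt(ex, 0)
      # extending by ANY incident graph edge (not just host edges) kills safety
      for (e in which(g$edges$from == g$edges$to[p[length(p)]]))
        expect_lte(ex - extend_delta(idx, e, "end"), 0)
      for (e in which(g$edges$to == g$edges$from[p[1]]))
        expect_lte(ex - extend_delta(idx, e, "start"), 0)
    }
  }
})

test_that("the expanded set does not depend on the seeding decomposition", {
  set.seed(53)
  for (i in 1:10) {
    inst <- simulate_splice_instance(sim_config(k = sample(2:10, 1),
                                                seed = sample.int(1e6, 1)))
    g <- inst$graph
    a <- enumerate_maximal_safe_paths(g, simple_flow_decomposition(g))
    b <- enumerate_maximal_safe_paths(g, greedy_width_decomposition(g))
    expect_setequal(canon_path_set(expand_concise(a)),
                    canon_path_set(expand_concise(b)))
  }
})

test_that("windows inside an entry overlap-or-touch and respect invariants", {
  set.seed(59)
  for (i in 1:8) {
    inst <- simulate_splice_instance(sim_config(k = sample(3:10, 1),
                                                seed = sample.int(1e6, 1)))
    cp <- enumerate_maximal_safe_paths(inst$graph)
    for (e in cp$entries) {
      w <- e$windows
      expect_true(all(w$left >= 1L & w$right <= length(e$edge_ids)))
      expect_true(all(w$left <= w$right))
      expect_true(all(w$excess > 0))
      if (nrow(w) > 1L) {
        expect_true(all(diff(w$left) > 0))          # none contains another
        expect_true(all(diff(w$right) > 0))
        expect_true(all(w$left[-1] <= w$right[-nrow(w)] + 1L))  # chained
      }
    }
  }
})

test_that("enumeration rejects an invalid decomposition", {
  g1 <- make_g1()
  d <- simple_flow_decomposition(g1)
  d$paths[[1]]$weight <- d$paths[[1]]$weight + 1
  expect_error(enumerate_maximal_safe_paths(g1, d), "invalid decomposition")
})
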