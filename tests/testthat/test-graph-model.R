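test_that("graph files parse with file-order edge ids and 0-based labels", {
  f <- tmpfile()
  writeLines(c("# g1", "4", "0 1 1", "1 3 1", "0 2 2", "2 3 2"), f)
  gs <- read_flow_graphs(f)
  expect_length(gs, 1L)
  g <- gs[[1]]
  expect_equal(g$name, "g1")
  expect_equal(g$n, 4L)
  expect_equal(nrow(g$edges), 4L)
  expect_equal(g$edges$from, c(1L, 2L, 1L, 3L))  # shifted to 1-based
  expect_equal(g$edges$weight, c(1, 1, 2, 2))
  expect_true(g$integer_mode)
})

test_that("multi-record files load in file order and malformed input errors", {
  f <- tmpfile()
  writeLines(c("# a", "3", "0 1 2", "1 2 2", "# b", "2", "0 1 5"), f)
  gs <- read_flow_graphs(f)
  expect_equal(vapply(gs, `[[`, character(1), "name"), c("a", "b"))

  writeLines(c("# bad", "4", "0 5 1"), f)
  expect_error(read_flow_graphs(f), "out of range")
  writeLines(c("# bad", "4", "0 1 0"), f)
  expect_error(read_flow_graphs(f), "nonpositive")
  writeLines(c("# bad", "4", "0 1"), f)
  expect_error(read_flow_graphs(f), "expected 'u v w'")
  writeLines(c("3", "0 1 1"), f)
  expect_error(read_flow_graphs(f), "header")
})

test_that("write-read round-trip is the identity, including parallel edges", {
  g1 <- make_g1()
  gp <- flow_graph(4, data.frame(from = c(1, 1, 2, 3, 3),
                                 to = c(2, 2, 3, 4, 4),
                                 weight = c(1.5, 2, 3.5, 2, 1.5)),
                   name = "par")
  f <- tmpfile()
  write_flow_graphs(list(g1, gp), f)
  back <- read_flow_graphs(f)
  expect_equal(back[[1]]$edges, g1$edges)
  expect_equal(back[[2]]$edges, gp$edges)   # parallel edges, order preserved
  expect_equal(back[[2]]$n, gp$n)

  write_flow_graphs(list(), f)
  expect_length(read_flow_graphs(f), 0L)
})

test_that("validation reports conservation, cycle and multiplicity violations", {
  expect_equal(nrow(validate_flow_graph(make_g1())), 0L)

  bad <- flow_graph(4, data.frame(from = c(1, 2, 1, 3), to = c(2, 4, 3, 4),
                                  weight = c(1, 2, 2, 2)), validate = FALSE)
  rep <- validate_flow_graph(bad)
  expect_true(any(rep$kind == "conservation"))
  expect_match(rep$message[rep$kind == "conservation"][1], "vertex 2")

  cyc <- flow_graph(4, data.frame(from = c(1, 2, 1, 3, 4),
                                  to = c(2, 4, 3, 4, 1),
                                  weight = c(1, 1, 2, 2, 1)), validate = FALSE)
  expect_true(any(validate_flow_graph(cyc)$kind == "cycle"))

  two_src <- flow_graph(4, data.frame(from = c(1, 2, 3), to = c(3, 3, 4),
                                      weight = c(1, 1, 2)), validate = FALSE)
  expect_true(any(validate_flow_graph(two_src)$kind == "source"))
  expect_error(flow_graph(4, two_src$edges), "invalid flow graph")
})

test_that("augmenting multi-source graphs restores a unique source/sink", {
  g <- flow_graph(4, data.frame(from = c(1, 2, 3, 3), to = c(3, 3, 4, 4),
                                weight = c(1, 2, 1, 2)),
                  augment = TRUE)
  expect_equal(g$n, 6L)
  expect_equal(flow_source(g), 5L)
  expect_equal(g$artificial_st, c(5L, 6L))
  expect_equal(nrow(validate_flow_graph(g)), 0L)
})

test_that("topological order is deterministic with smallest-label ties", {
  expect_equal(topological_order(make_g1()), c(1L, 2L, 3L, 4L))
  chain <- flow_graph(3, data.frame(from = c(1, 2), to = c(2, 3), weight = 7))
  expect_equal(topological_order(chain), 1:3)
  cyc <- flow_graph(3, data.frame(from = c(1, 2, 3), to = c(2, 3, 2),
                                  weight = 1), validate = FALSE)
  expect_error(topological_order(cyc), "cyclic")
})

test_that("in/out flow sums edges in one pass, including parallel edges", {
  io <- in_out_flow(make_g1())
  expect_equal(io$fin[4], 3)
  expect_equal(io$fout[1], 3)
  expect_equal(io$fin[2], 1); expect_equal(io$fout[2], 1)

  gp <- flow_graph(2, data.frame(from = c(1, 1), to = c(2, 2),
                                 weight = c(2, 3)))
  expect_equal(in_out_flow(gp)$fout[1], 5)

  iso <- flow_graph(3, data.frame(from = 1, to = 3, weight = 2),
                    validate = FALSE)
  expect_equal(in_out_flow(iso)$fin[2], 0)
  expect_equal(in_out_flow(iso)$fout[2], 0)
})

test_that("total flow bookkeeping identities hold on random graphs", {
  set.seed(42)
  for (i in 1:20) {
    g <- random_guarded_graph()
    io <- in_out_flow(g)
    expect_equal(sum(io$fin), sum(io$fout))
    expect_equal(sum(io$fin), sum(g$edges$weight))
    expect_equal(io$fout[flow_source(g)], io$fin[flow_sink(g)])
    expect_equal(io$fin[flow_source(g)], 0)
    expect_equal(io$fout[flow_sink(g)], 0)
  }
})

test_that("truth and node-length files round-trip", {
  recs <- list(list(name = "a",
                    transcripts = list(list(vertices = c(1L, 2L, 4L), weight = 2),
                                       list(vertices = c(1L, 3L, 4L), weight = 1))))
  f <- tmpfile()
  write_truth_paths(recs, f)
  back <- read_truth_paths(f)
  expect_equal(back[[1]]$transcripts, recs[[1]]$transcripts)

  writeLines(c("# a", "0 100", "2 250"), f)
  lens <- read_node_lengths(f, 4L)
  expect_equal(lens[[1]]$lengths, c(100, NA, 250, NA))
})

test_that("path_vertices validates contiguity and rejects empty paths", {
  g <- make_g2()
  expect_equal(path_vertices(g, c(1, 2, 4)), c(1L, 2L, 3L, 5L))
  expect_error(path_vertices(g, c(1, 4)), "contiguous")
  expect_error(path_vertices(g, integer(0)), "empty")
})
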