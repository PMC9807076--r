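#' Read flow graphs from a Catfish-style multigraph file
#'
#' A file holds one or more records. Each record is a header line
#' `# <name>`, a line with the vertex count `n`, then one line `u v w` per
#' edge with 0-based vertex labels and a positive (integer or decimal)
#' weight. Edge ids are assigned by file order; vertices mentioned by no
#' edge still exist if `< n`. Vertex labels are converted to the package's
#' internal 1-based labelling.
#'
#' @param path File to read.
#' @param validate Validate each graph (default `TRUE`).
#' @param augment Passed to [flow_graph()]: repair multiple sources/sinks
#'   with a global source/sink pair.
#' @return A list of `flow_graph` objects in file order.
#' @export
read_flow_graphs <- function(path, validate = TRUE, augment = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  keep <- !grepl("^\\s*$", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  graphs <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!startsWith(lines[i], "#"))
      stop(sprintf("line %d: expected '# <name>' header, got '%s'",
                   lineno[i], lines[i]))
    name <- trimws(sub("^#", "", lines[i]))
    i <- i + 1L
    if (i > length(lines))
      stop(sprintf("line %d: record '%s' missing vertex count", lineno[i - 1L], name))
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n < 1L)
      stop(sprintf("line %d: bad vertex count '%s'", lineno[i], lines[i]))
    i <- i + 1L
    from <- integer(0); to <- integer(0); w <- numeric(0)
    while (i <= length(lines) && !startsWith(lines[i], "#")) {
      tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
      if (length(tok) != 3L)
        stop(sprintf("line %d: expected 'u v w', got '%s'", lineno[i], lines[i]))
      u <- suppressWarnings(as.integer(tok[1]))
      v <- suppressWarnings(as.integer(tok[2]))
      wt <- suppressWarnings(as.numeric(tok[3]))
      if (is.na(u) || is.na(v) || is.na(wt))
        stop(sprintf("line %d: unparsable edge '%s'", lineno[i], lines[i]))
      if (u < 0L || u >= n || v < 0L || v >= n)
        stop(sprintf("line %d: vertex out of range 0..%d in '%s'",
                     lineno[i], n - 1L, lines[i]))
      if (wt <= 0)
        stop(sprintf("line %d: nonpositive weight in '%s'", lineno[i], lines[i]))
      from <- c(from, u + 1L); to <- c(to, v + 1L); w <- c(w, wt)
      i <- i + 1L
    }
    graphs[[length(graphs) + 1L]] <-
      flow_graph(n, data.frame(from = from, to = to, weight = w),
                 name = name, validate = validate, augment = augment)
  }
  graphs
}

fmt_weight <- function(w) {
  ifelse(w == round(w), format(w, scientific = FALSE, trim = TRUE),
         formatC(w, digits = 15, format = "g"))
}

#' Write flow graphs to a Catfish-style multigraph file
#'
#' Inverse of [read_flow_graphs()]: round-tripping reproduces vertex
#' counts, edge lists (including parallel edges, order preserved) and
#' weights exactly.
#'
#' @param graphs A list of `flow_graph` objects (or a single one).
#' @param path Output file.
#' @export
write_flow_graphs <- function(graphs, path) {
  if (inherits(graphs, "flow_graph")) graphs <- list(graphs)
  out <- character(0)
  for (g in graphs) {
    out <- c(out, paste("#", g$name), as.character(g$n),
             sprintf("%d %d %s", g$edges$from - 1L, g$edges$to - 1L,
                     fmt_weight(g$edges$weight)))
  }
  writeLines(out, path)
  invisible(NULL)
}

#' Read or write ground-truth transcript files
#'
#' Truth files mirror the graph files: a `# <name>` header per record, then
#' one line per transcript `w v0 v1 ... vk` — a weight followed by a
#' 0-based source-to-sink vertex path.
#'
#' @param path File to read or write.
#' @return `read_truth_paths` returns a list of records, each a list with
#'   `name` and `transcripts` (a list of `list(vertices, weight)` with
#'   1-based vertices).
#' @export
read_truth_paths <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*$", lines)]
  records <- list()
  cur <- NULL
  for (ln in lines) {
    if (startsWith(ln, "#")) {
      if (!is.null(cur)) records[[length(records) + 1L]] <- cur
      cur <- list(name = trimws(sub("^#", "", ln)), transcripts = list())
    } else {
      if (is.null(cur)) stop("truth file must start with a '# <name>' header")
      tok <- as.numeric(strsplit(trimws(ln), "\\s+")[[1]])
      if (length(tok) < 3L || anyNA(tok))
        stop("bad truth line: ", ln)
      cur$transcripts[[length(cur$transcripts) + 1L]] <-
        list(vertices = as.integer(tok[-1L]) + 1L, weight = tok[1L])
    }
  }
  if (!is.null(cur)) records[[length(records) + 1L]] <- cur
  records
}

#' @rdname read_truth_paths
#' @param records List of records as returned by `read_truth_paths`, or a
#'   list of `list(name, transcripts)` built in code.
#' @export
write_truth_paths <- function(records, path) {
  out <- character(0)
  for (rec in records) {
    out <- c(out, paste("#", rec$name),
             vapply(rec$transcripts, function(tr) {
               paste(c(fmt_weight(tr$weight), tr$vertices - 1L), collapse = " ")
             }, character(1)))
  }
  writeLines(out, path)
  invisible(NULL)
}

#' Read per-node base lengths
#'
#' Format: `# <name>` header per record, then `v length` lines with
#' 0-based vertex labels and positive integer base counts.
#'
#' @param path File to read.
#' @return A list of records `list(name, lengths)`; `lengths` is a numeric
#'   vector indexed by 1-based vertex, `NA` for unlisted vertices.
#' @param n Number of vertices per record (recycled if length 1).
#' @export
read_node_lengths <- function(path, n) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*$", lines)]
  records <- list()
  cur <- NULL
  idx <- 0L
  for (ln in lines) {
    if (startsWith(ln, "#")) {
      if (!is.null(cur)) records[[length(records) + 1L]] <- cur
      idx <- idx + 1L
      ni <- if (length(n) == 1L) n else n[idx]
      cur <- list(name = trimws(sub("^#", "", ln)), lengths = rep(NA_real_, ni))
    } else {
      tok <- as.numeric(strsplit(trimws(ln), "\\s+")[[1]])
      if (length(tok) != 2L || anyNA(tok)) stop("bad length line: ", ln)
      cur$lengths[as.integer(tok[1L]) + 1L] <- tok[2L]
    }
  }
  if (!is.null(cur)) records[[length(records) + 1L]] <- cur
  records
}
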