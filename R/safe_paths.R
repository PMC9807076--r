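#' Maximal safe windows on one decomposition path
#'
#' Two-pointer scan: the window `[l, r]` (inclusive edge positions on the
#' host path) is grown on the right for as long as the excess flow stays
#' positive, updated in constant time per move from the extension deltas;
#' when the right pointer is stuck, the window is emitted unless its right
#' end does not exceed the previously emitted one (which would make it
#' nested), and the left pointer advances. Every single-edge window is safe
#' (excess equals the edge weight), so the scan never stalls. Each pointer
#' advances at most `|host|` times, so the scan is linear in the host
#' length. Emitted windows are exactly the subpaths of the host that are
#' safe and cannot be extended along the host without losing safety.
#'
#' @param x A `flow_graph` or [safety_index()].
#' @param edge_ids The host path (contiguous edge ids), typically one path
#'   of a flow decomposition.
#' @return A data frame with columns `left`, `right` (1-based inclusive
#'   edge positions on the host) and `excess`.
#' @export
maximal_safe_paths_on_path <- function(x, edge_ids) {
  idx <- as_safety_index(x)
  g <- idx$graph
  verts <- path_vertices(g, edge_ids)
  w <- g$edges$weight[edge_ids]
  L <- length(edge_ids)
  # dend[j]: excess drop when appending host edge j to a window ending at j-1
  # gain[l]: excess gain when dropping host edge l from the window's start
  dend <- c(NA_real_, idx$fout[verts[2:L]] - w[-1L])[seq_len(L)]
  if (L == 1L) dend <- NA_real_
  gain <- idx$fin[verts[2:(L + 1L)]] - w
  eps <- idx$tol
  l <- 1L; r <- 1L; ex <- w[1L]; lastr <- 0L
  out_l <- integer(0); out_r <- integer(0); out_e <- numeric(0)
  repeat {
    while (r < L && ex - dend[r + 1L] > eps) {
      r <- r + 1L
      ex <- ex - dend[r]
    }
    if (r > lastr) {
      out_l <- c(out_l, l); out_r <- c(out_r, r); out_e <- c(out_e, ex)
      lastr <- r
    }
    if (r == L) break
    if (l == r) {
      l <- l + 1L; r <- l; ex <- w[l]
    } else {
      ex <- ex + gain[l]
      l <- l + 1L
    }
  }
  data.frame(left = out_l, right = out_r, excess = out_e)
}

#' Deduplicate paths under substring containment
#'
#' Removes exact duplicates (first occurrence kept) and every sequence that
#' occurs as a contiguous substring of a longer one. Matching operates on
#' edge-id sequences, so parallel edges are unambiguous. Removing interior
#' substrings (not only prefixes/suffixes) is required for completeness: a
#' path maximal within one decomposition path may sit strictly inside a
#' longer safe path discovered on another.
#'
#' @param paths List of integer edge-id vectors.
#' @return Sublist of `paths` in original order.
#' @export
deduplicate_subpaths <- function(paths) {
  if (length(paths) <= 1L) return(paths)
  keys <- vapply(paths, seq_key, character(1))
  lens <- lengths(paths)
  keep <- !duplicated(keys)
  ord <- order(lens, decreasing = TRUE)
  for (i in seq_along(paths)) {
    if (!keep[i]) next
    for (j in ord) {
      if (lens[j] <= lens[i]) break
      if (keep[j] && grepl(keys[i], keys[j], fixed = TRUE)) {
        keep[i] <- FALSE
        break
      }
    }
  }
  paths[keep]
}

#' Enumerate all maximal safe paths of a flow graph
#'
#' Runs the two-pointer scan on every path of a flow decomposition, then
#' assembles the *concise representation*: per host path, overlapping or
#' touching maximal-safe windows are merged into one minimal-length host
#' subpath carrying the window offsets; across hosts, windows whose edge
#' sequence is a duplicate or a contiguous substring of a window found
#' elsewhere are removed. Every maximal safe path of the graph is w-safe
#' for some w >= 1 and therefore appears as a subpath of some path in every
#' decomposition, so the expanded window set equals the set of all maximal
#' safe paths regardless of which decomposition seeds the scan.
#'
#' @param g A valid `flow_graph`.
#' @param d A `flow_decomposition` of `g`; defaults to
#'   [simple_flow_decomposition()].
#' @return An object of class `concise_paths`: list with `entries`, each
#'   `list(host, edge_ids, windows)` where `windows` is a data frame of
#'   1-based inclusive `left`/`right` offsets into `edge_ids` plus the
#'   window's `excess`.
#' @export
enumerate_maximal_safe_paths <- function(g, d = simple_flow_decomposition(g)) {
  ok <- verify_decomposition(g, d)
  if (!ok)
    stop("invalid decomposition: ", paste(attr(ok, "diagnostics"), collapse = "; "))
  idx <- safety_index(g)
  win_host <- integer(0); win_l <- integer(0); win_r <- integer(0)
  win_ex <- numeric(0)
  win_paths <- list()
  for (h in seq_along(d$paths)) {
    host <- d$paths[[h]]$edge_ids
    wins <- maximal_safe_paths_on_path(idx, host)
    for (i in seq_len(nrow(wins))) {
      win_host <- c(win_host, h)
      win_l <- c(win_l, wins$left[i]); win_r <- c(win_r, wins$right[i])
      win_ex <- c(win_ex, wins$excess[i])
      win_paths[[length(win_paths) + 1L]] <- host[wins$left[i]:wins$right[i]]
    }
  }
  kept_paths <- deduplicate_subpaths(win_paths)
  kept_keys <- vapply(kept_paths, seq_key, character(1))
  keys <- vapply(win_paths, seq_key, character(1))
  keep <- !duplicated(keys) & keys %in% kept_keys
  entries <- list()
  for (h in unique(win_host[keep])) {
    sel <- which(keep & win_host == h)
    sel <- sel[order(win_l[sel])]
    host <- d$paths[[h]]$edge_ids
    start <- 1L
    repeat {
      # merge run of windows that overlap or touch (share >= 1 vertex)
      end <- start
      maxr <- win_r[sel[start]]
      while (end < length(sel) && win_l[sel[end + 1L]] <= maxr + 1L) {
        end <- end + 1L
        maxr <- max(maxr, win_r[sel[end]])
      }
      lo <- win_l[sel[start]]
      entries[[length(entries) + 1L]] <- list(
        host = h,
        edge_ids = host[lo:maxr],
        windows = data.frame(left = win_l[sel[start:end]] - lo + 1L,
                             right = win_r[sel[start:end]] - lo + 1L,
                             excess = win_ex[sel[start:end]]))
      if (end == length(sel)) break
      start <- end + 1L
    }
  }
  structure(list(entries = entries, provenance = d$provenance),
            class = "concise_paths")
}

#' @export
print.concise_paths <- function(x, ...) {
  nw <- sum(vapply(x$entries, function(e) nrow(e$windows), integer(1)))
  cat(sprintf("<concise_paths: %d entries, %d maximal safe paths, size %d edges>\n",
              length(x$entries), nw, concise_size(x)))
  invisible(x)
}

#' Expand a concise representation into explicit paths
#'
#' Materializes every window as an explicit edge-id path. The expanded
#' total size can be quadratically larger than the concise representation.
#'
#' @param x A `concise_paths` object.
#' @return List of integer edge-id vectors (all maximal safe paths).
#' @export
expand_concise <- function(x) {
  out <- list()
  for (e in x$entries)
    for (i in seq_len(nrow(e$windows)))
      out[[length(out) + 1L]] <- e$edge_ids[e$windows$left[i]:e$windows$right[i]]
  out
}

#' Size of a concise representation
#'
#' Total number of edges stored across entry subpaths (the `|Pc|` measure).
#'
#' @param x A `concise_paths` object.
#' @return Integer edge count.
#' @export
concise_size <- function(x) {
  sum(vapply(x$entries, function(e) length(e$edge_ids), integer(1)))
}
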