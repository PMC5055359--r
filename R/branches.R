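#' Extract branches from a centreline graph
#'
#' A branch is a maximal chain of connected segments without any furcation:
#' a path whose endpoints have degree other than 2 and whose interior nodes
#' all have degree 2. A connected component made entirely of degree-2 nodes
#' (a pure cycle) is reported as a single closed branch.
#'
#' @param graph a `centerline_graph`.
#' @return An object of class `branch_set`: a data frame with one row per
#'   branch (`branch`, `length`, `n_edges`, `closed`, `path` as a
#'   comma-separated node-id string).
#' @export
extract_branches <- function(graph) {
  m <- n_edges(graph)
  out <- list()
  if (m > 0) {
    inc <- incident_edges(graph)
    deg <- graph$nodes$degree
    visited <- logical(m)
    # walk from every non-degree-2 node along each incident edge
    anchors <- which(deg != 2)
    for (v0 in anchors) {
      for (e0 in inc[[v0]]) {
        if (visited[e0]) next
        path <- v0
        len <- 0
        ne <- 0L
        v <- v0
        e <- e0
        repeat {
          visited[e] <- TRUE
          len <- len + graph$edges$length[e]
          ne <- ne + 1L
          v <- neighbor_of(graph, e, v)
          path <- c(path, v)
          if (deg[v] != 2) break
          nxt <- setdiff(inc[[v]], e)
          if (length(nxt) == 0 || visited[nxt[1]]) break
          e <- nxt[1]
        }
        out[[length(out) + 1]] <- list(path = path, length = len,
                                       n_edges = ne, closed = FALSE)
      }
    }
    # remaining edges belong to pure cycles of degree-2 nodes
    for (e0 in which(!visited)) {
      if (visited[e0]) next
      v0 <- graph$edges$from[e0]
      path <- v0
      len <- 0
      ne <- 0L
      v <- v0
      e <- e0
      repeat {
        visited[e] <- TRUE
        len <- len + graph$edges$length[e]
        ne <- ne + 1L
        v <- neighbor_of(graph, e, v)
        path <- c(path, v)
        nxt <- setdiff(inc[[v]], e)
        nxt <- nxt[!visited[nxt]]
        if (length(nxt) == 0) break
        e <- nxt[1]
      }
      out[[length(out) + 1]] <- list(path = path, length = len,
                                     n_edges = ne, closed = TRUE)
    }
  }
  br <- if (length(out) == 0) {
    data.frame(branch = integer(), length = numeric(), n_edges = integer(),
               closed = logical(), path = character(),
               stringsAsFactors = FALSE)
  } else {
    data.frame(
      branch = seq_along(out),
      length = vapply(out, `[[`, numeric(1), "length"),
      n_edges = vapply(out, `[[`, integer(1), "n_edges"),
      closed = vapply(out, `[[`, logical(1), "closed"),
      path = vapply(out, function(b)
        paste(graph$nodes$id[b$path], collapse = ","), character(1)),
      stringsAsFactors = FALSE)
  }
  class(br) <- c("branch_set", "data.frame")
  br
}

#' Summarise branch lengths
#'
#' Mean, median and histogram of branch lengths; the default 25-micrometre
#' bins cover the range observed in distal Purkinje reconstructions (modal
#' branches near 50 um, maxima around 300 um).
#'
#' @param branches a `branch_set` from [extract_branches()].
#' @param bin_width histogram bin width in micrometres (default 25).
#' @return A list with `n`, `mean`, `median`, `sd`, `max` and `histogram`
#'   (data frame of `lower`, `upper`, `count`).
#' @export
branch_stats <- function(branches, bin_width = 25) {
  if (nrow(branches) == 0) stopf("no branches to summarise")
  len <- branches$length
  top <- max(300, ceiling(max(len) / bin_width) * bin_width)
  breaks <- seq(0, top, by = bin_width)
  h <- graphics::hist(len, breaks = breaks, plot = FALSE)
  list(n = length(len), mean = mean(len), median = stats::median(len),
       sd = stats::sd(len), max = max(len),
       histogram = data.frame(lower = utils::head(breaks, -1),
                              upper = breaks[-1], count = h$counts))
}

#' Furcation angles of a centreline graph
#'
#' At every furcation node (degree >= 3) the angle between each unordered
#' pair of incident segments is measured from the two outward unit vectors
#' (node towards adjacent landmark). A degree-3 'Y' yields three angles; a
#' degree-k node yields `choose(k, 2)`. Angles strictly below 90 degrees are
#' classed acute (`alpha`), all others obtuse (`beta`) -- exactly 90 degrees
#' falls in `beta`, as the acute population is observed on the open interval
#' up to 90.
#'
#' @param graph a `centerline_graph` with finite node coordinates.
#' @return An object of class `furcation_angles`: data frame with columns
#'   `node` (id), `angle` (degrees), `class` (`alpha`/`beta`), `to_a`, `to_b`
#'   (ids of the two adjacent landmarks).
#' @export
furcation_angles <- function(graph) {
  if (any(!is.finite(as.matrix(graph$nodes[, c("x", "y", "z")])))) {
    stopf("furcation angles need node coordinates")
  }
  inc <- incident_edges(graph)
  xyz <- as.matrix(graph$nodes[, c("x", "y", "z")])
  rows <- list()
  for (v in which(graph$nodes$degree >= 3)) {
    nbs <- vapply(inc[[v]], function(e) neighbor_of(graph, e, v), integer(1))
    vecs <- lapply(nbs, function(u) {
      d <- xyz[u, ] - xyz[v, ]
      if (vnorm(d) == 0) {
        stopf("coincident landmarks %s and %s", graph$nodes$id[v],
              graph$nodes$id[u])
      }
      d / vnorm(d)
    })
    cmb <- utils::combn(seq_along(nbs), 2)
    for (k in seq_len(ncol(cmb))) {
      i <- cmb[1, k]; j <- cmb[2, k]
      ang <- angle_between(vecs[[i]], vecs[[j]])
      rows[[length(rows) + 1]] <- data.frame(
        node = graph$nodes$id[v], angle = ang,
        class = if (ang < 90) "alpha" else "beta",
        to_a = graph$nodes$id[nbs[i]], to_b = graph$nodes$id[nbs[j]],
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(node = character(), angle = numeric(), class = character(),
               to_a = character(), to_b = character(), stringsAsFactors = FALSE)
  class(out) <- c("furcation_angles", "data.frame")
  out
}
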