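#' Spatially embedded centreline graphs
#'
#' A `centerline_graph` is an undirected graph whose nodes are labelled 3D
#' landmarks (micrometres) joined by straight segments; each edge carries its
#' Euclidean length. Node roles follow degree: `terminal` (degree 1),
#' `pass_through` (degree 2), `furcation` (degree >= 3).
#'
#' @param landmarks a [landmark_set].
#' @param edges two-column matrix/data frame of landmark ids (one undirected
#'   edge per row), as returned by [read_edge_list()].
#' @return An object of class `centerline_graph`: a list with `nodes` (data
#'   frame `id`, `x`, `y`, `z`, `degree`, `role`) and `edges` (data frame
#'   `from`, `to`, `length`, with `from`/`to` as 1-based node indices).
#' @examples
#' lm <- landmark_set(c("A", "B"), c(0, 3), c(0, 4), c(0, 0))
#' g <- build_graph(lm, cbind("A", "B"))
#' g$edges$length  # 5
#' @export
build_graph <- function(landmarks, edges) {
  stopifnot(inherits(landmarks, "landmark_set"))
  edges <- as.matrix(edges)
  if (ncol(edges) < 2) stopf("edge list must have two columns")
  from <- match(as.character(edges[, 1]), landmarks$id)
  to <- match(as.character(edges[, 2]), landmarks$id)
  miss <- which(is.na(from) | is.na(to))
  if (length(miss)) {
    stopf("edge %d references unknown landmark id '%s'", miss[1],
          edges[miss[1], which(is.na(c(from[miss[1]], to[miss[1]])))[1]])
  }
  loops <- which(from == to)
  if (length(loops)) {
    stopf("self-loop %s-%s not allowed", edges[loops[1], 1], edges[loops[1], 2])
  }
  key <- paste(pmin(from, to), pmax(from, to))
  if (anyDuplicated(key)) {
    d <- which(duplicated(key))[1]
    stopf("duplicate edge %s-%s", edges[d, 1], edges[d, 2])
  }
  xyz <- as.matrix(landmarks[, c("x", "y", "z")])
  len <- sqrt(rowSums((xyz[from, , drop = FALSE] - xyz[to, , drop = FALSE])^2))
  zero <- which(len == 0)
  if (length(zero)) {
    stopf("zero-length edge %s-%s", edges[zero[1], 1], edges[zero[1], 2])
  }
  graph_from_edges(cbind(from, to), coords = xyz, ids = landmarks$id,
                   lengths = len)
}

#' Build a centreline graph from raw indices
#'
#' Lower-level constructor used by the synthetic generator, the null models
#' and abstract (non-spatial) test graphs. When `coords` is omitted the graph
#' is purely topological and every edge gets unit length unless `lengths` is
#' given.
#'
#' @param edges two-column integer matrix of 1-based node indices.
#' @param coords optional `n x 3` coordinate matrix (micrometres).
#' @param ids optional node labels (defaults to `N1..Nn`).
#' @param lengths optional edge lengths; computed from `coords` when
#'   available, else 1.
#' @param n_nodes number of nodes (defaults to `max(edges)` or `nrow(coords)`).
#' @return A `centerline_graph`.
#' @export
graph_from_edges <- function(edges, coords = NULL, ids = NULL, lengths = NULL,
                             n_nodes = NULL) {
  edges <- matrix(as.integer(as.matrix(edges)), ncol = 2)
  if (is.null(n_nodes)) {
    n_nodes <- if (!is.null(coords)) nrow(coords)
               else if (nrow(edges) > 0) max(edges) else 0L
  }
  if (nrow(edges) > 0 && (min(edges) < 1 || max(edges) > n_nodes)) {
    stopf("edge indices out of range 1..%d", n_nodes)
  }
  if (nrow(edges) > 0 && any(edges[, 1] == edges[, 2])) stopf("self-loop not allowed")
  key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  if (anyDuplicated(key)) stopf("duplicate edge")
  if (is.null(coords)) {
    coords <- matrix(NA_real_, n_nodes, 3)
  }
  if (is.null(lengths)) {
    if (all(is.finite(coords)) && nrow(edges) > 0) {
      lengths <- sqrt(rowSums((coords[edges[, 1], , drop = FALSE] -
                                 coords[edges[, 2], , drop = FALSE])^2))
    } else {
      lengths <- rep(1, nrow(edges))
    }
  }
  if (any(lengths <= 0)) stopf("edge lengths must be positive")
  if (is.null(ids)) ids <- paste0("N", seq_len(n_nodes))
  deg <- tabulate(c(edges[, 1], edges[, 2]), nbins = n_nodes)
  nodes <- data.frame(id = as.character(ids), x = coords[, 1], y = coords[, 2],
                      z = coords[, 3], degree = deg,
                      role = node_role(deg), stringsAsFactors = FALSE)
  g <- list(nodes = nodes,
            edges = data.frame(from = edges[, 1], to = edges[, 2],
                               length = as.numeric(lengths)))
  class(g) <- "centerline_graph"
  g
}

node_role <- function(deg) {
  ifelse(deg <= 1, ifelse(deg == 0, "isolated", "terminal"),
         ifelse(deg == 2, "pass_through", "furcation"))
}

#' @export
print.centerline_graph <- function(x, ...) {
  r <- table(factor(x$nodes$role,
                    levels = c("isolated", "terminal", "pass_through",
                               "furcation")))
  cat(sprintf("<centerline_graph> %d nodes, %d edges\n",
              nrow(x$nodes), nrow(x$edges)))
  cat(sprintf("  terminals %d, pass-through %d, furcations %d, isolated %d\n",
              r[["terminal"]], r[["pass_through"]], r[["furcation"]],
              r[["isolated"]]))
  if (nrow(x$edges) > 0) {
    cat(sprintf("  total centreline length %.1f um\n", sum(x$edges$length)))
  }
  invisible(x)
}

#' Number of nodes / edges
#' @param graph a `centerline_graph`.
#' @return Integer count.
#' @export
n_nodes <- function(graph) nrow(graph$nodes)

#' @rdname n_nodes
#' @export
n_edges <- function(graph) nrow(graph$edges)

# Adjacency list: for each node, the indices of incident edges.
incident_edges <- function(graph) {
  n <- n_nodes(graph)
  inc <- vector("list", n)
  for (e in seq_len(n_edges(graph))) {
    i <- graph$edges$from[e]; j <- graph$edges$to[e]
    inc[[i]] <- c(inc[[i]], e)
    inc[[j]] <- c(inc[[j]], e)
  }
  inc
}

neighbor_of <- function(graph, e, v) {
  ifelse(graph$edges$from[e] == v, graph$edges$to[e], graph$edges$from[e])
}

# Connected component labels by BFS.
components_of <- function(graph) {
  n <- n_nodes(graph)
  inc <- incident_edges(graph)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- vapply(inc[[v]], function(e) neighbor_of(graph, e, v), integer(1))
      fresh <- nb[comp[nb] == 0L]
      comp[fresh] <- cur
      queue <- c(queue, fresh)
    }
  }
  comp
}

#' Is the graph connected?
#' @param graph a `centerline_graph`.
#' @return Logical.
#' @export
is_connected <- function(graph) {
  n_nodes(graph) <= 1 || max(components_of(graph)) == 1
}

# Dense symmetric length matrix (Inf off-graph, 0 diagonal).
length_matrix <- function(graph, mode = c("weighted", "binary")) {
  mode <- match.arg(mode)
  n <- n_nodes(graph)
  W <- matrix(Inf, n, n)
  diag(W) <- 0
  len <- if (mode == "binary") rep(1, n_edges(graph)) else graph$edges$length
  for (e in seq_len(n_edges(graph))) {
    i <- graph$edges$from[e]; j <- graph$edges$to[e]
    if (len[e] < W[i, j]) {
      W[i, j] <- len[e]
      W[j, i] <- len[e]
    }
  }
  W
}
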