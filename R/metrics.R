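#' All-pairs shortest path matrix
#'
#' Geodesic distances over edge lengths. In `weighted` mode (the default)
#' shortest paths minimise the summed Euclidean edge length, which is the
#' inverse of the conventional connection weight `w = 1/length`; in `binary`
#' mode every edge counts 1 and distances are hop counts. Unreachable pairs
#' are `Inf`, the diagonal is 0.
#'
#' @param graph a `centerline_graph`.
#' @param mode `"weighted"` or `"binary"`.
#' @return An `n x n` symmetric numeric matrix.
#' @export
shortest_path_matrix <- function(graph, mode = c("weighted", "binary")) {
  mode <- match.arg(mode)
  D <- apsp_of(graph, mode)
  dimnames(D) <- list(graph$nodes$id, graph$nodes$id)
  D
}

# Dispatch: BFS hop counts in binary mode, Floyd-Warshall on the dense
# length matrix in weighted mode.
apsp_of <- function(graph, mode) {
  if (mode == "binary") {
    cpp_bfs_apsp(n_nodes(graph), graph$edges$from - 1L, graph$edges$to - 1L)
  } else {
    cpp_apsp(length_matrix(graph, mode))
  }
}

#' Global efficiency
#'
#' The averaged inverse shortest path length over all ordered node pairs,
#' with unreachable pairs contributing zero. A measure of network
#' integration: 1 for a complete unit-length graph, 0 for an edgeless one.
#'
#' @inheritParams shortest_path_matrix
#' @return A single number (dimensionless in binary mode, inverse
#'   micrometres in weighted mode).
#' @export
global_efficiency <- function(graph, mode = c("weighted", "binary")) {
  mode <- match.arg(mode)
  n <- n_nodes(graph)
  if (n < 2) stopf("global efficiency needs at least 2 nodes")
  D <- apsp_of(graph, mode)
  inv <- 1 / D
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  sum(inv) / (n * (n - 1))
}

#' Local efficiency
#'
#' For each node, the global efficiency of the subgraph induced by its
#' neighbours, with paths restricted to that subgraph; nodes with fewer than
#' two neighbours score 0. A measure of segregation: how efficiently the
#' neighbourhood communicates when the node itself is removed.
#'
#' @inheritParams shortest_path_matrix
#' @return A list with `per_node` (named numeric vector) and `mean`.
#' @export
local_efficiency <- function(graph, mode = c("weighted", "binary")) {
  mode <- match.arg(mode)
  le <- cpp_local_efficiency(length_matrix(graph, mode))
  names(le) <- graph$nodes$id
  list(per_node = le, mean = mean(le))
}

#' Node betweenness centrality
#'
#' Brandes accumulation with fractional counting over equal-length shortest
#' paths, on the same edge lengths as the efficiency measures. Values are
#' normalised by `(n-1)(n-2)/2`, the number of node pairs that could route
#' through a node of an undirected graph, so they lie in `[0, 1]`; terminal
#' nodes score 0.
#'
#' @inheritParams shortest_path_matrix
#' @param bins number of histogram bins over `[0, 1]` (default 10).
#' @return A list with `per_node` (named, normalised), `raw`, and
#'   `histogram` (data frame `lower`, `upper`, `count`).
#' @export
betweenness <- function(graph, mode = c("weighted", "binary"), bins = 10) {
  mode <- match.arg(mode)
  n <- n_nodes(graph)
  len <- if (mode == "binary") rep(1, n_edges(graph)) else graph$edges$length
  raw <- cpp_betweenness(n, graph$edges$from - 1L, graph$edges$to - 1L,
                         as.numeric(len))
  norm_const <- (n - 1) * (n - 2) / 2
  bn <- if (norm_const > 0) raw / norm_const else rep(0, n)
  names(bn) <- names(raw) <- graph$nodes$id
  breaks <- seq(0, 1, length.out = bins + 1)
  h <- graphics::hist(pmin(bn, 1), breaks = breaks, plot = FALSE)
  list(per_node = bn, raw = raw,
       histogram = data.frame(lower = utils::head(breaks, -1),
                              upper = breaks[-1], count = h$counts))
}

#' Degree assortativity
#'
#' Pearson correlation between the degrees at the two ends of each edge,
#' each undirected edge contributing its endpoint pair in both orders
#' (Newman's coefficient). Negative values indicate hubs preferentially
#' attached to low-degree nodes. When all edge endpoints have equal degree
#' the coefficient is undefined and `NA` is returned with
#' `attr(, "undefined") = TRUE`.
#'
#' @param graph a `centerline_graph` with at least one edge.
#' @return A number in `[-1, 1]`, or `NA` when undefined.
#' @export
assortativity <- function(graph) {
  if (n_edges(graph) == 0) stopf("assortativity needs at least one edge")
  deg <- graph$nodes$degree
  j <- c(deg[graph$edges$from], deg[graph$edges$to])
  k <- c(deg[graph$edges$to], deg[graph$edges$from])
  mjk <- mean(j * k)
  mj <- mean(j)
  denom <- mean(j^2) - mj^2
  if (denom == 0) {
    out <- NA_real_
    attr(out, "undefined") <- TRUE
    return(out)
  }
  r <- (mjk - mj^2) / denom
  attr(r, "undefined") <- FALSE
  r
}

#' Characteristic path length
#'
#' Mean shortest path length over all ordered pairs of distinct nodes,
#' excluding unreachable pairs; the number of excluded (infinite) pairs is
#' reported alongside.
#'
#' @inheritParams shortest_path_matrix
#' @return A list with `cpl` (micrometres in weighted mode, hops in binary)
#'   and `n_unreachable_pairs`.
#' @export
characteristic_path_length <- function(graph, mode = c("weighted", "binary")) {
  mode <- match.arg(mode)
  n <- n_nodes(graph)
  if (n < 2) stopf("characteristic path length needs at least 2 nodes")
  D <- apsp_of(graph, mode)
  off <- D[row(D) != col(D)]
  fin <- is.finite(off)
  if (!any(fin)) stopf("all node pairs unreachable")
  list(cpl = mean(off[fin]), n_unreachable_pairs = sum(!fin))
}

#' Complexity report for one network
#'
#' Bundles the complexity metrics used to characterise Purkinje centreline
#' networks: global/local efficiency, characteristic path length, degree
#' distribution, normalised betweenness and degree assortativity.
#'
#' @inheritParams shortest_path_matrix
#' @return An object of class `network_complexity`: a list with fields
#'   `mode`, `n_nodes`, `n_edges`, `global_efficiency`, `local_efficiency`
#'   (list), `characteristic_path_length` (list), `degree`, `betweenness`
#'   (list), `assortativity`, `assortativity_undefined`.
#' @export
network_complexity <- function(graph, mode = c("weighted", "binary")) {
  mode <- match.arg(mode)
  asr <- assortativity(graph)
  out <- list(
    mode = mode,
    n_nodes = n_nodes(graph),
    n_edges = n_edges(graph),
    global_efficiency = global_efficiency(graph, mode),
    local_efficiency = local_efficiency(graph, mode),
    characteristic_path_length = characteristic_path_length(graph, mode),
    degree = stats::setNames(graph$nodes$degree, graph$nodes$id),
    betweenness = betweenness(graph, mode),
    assortativity = as.numeric(asr),
    assortativity_undefined = isTRUE(attr(asr, "undefined")))
  class(out) <- "network_complexity"
  out
}

#' @export
print.network_complexity <- function(x, ...) {
  cat(sprintf("<network_complexity> %d nodes, %d edges (%s mode)\n",
              x$n_nodes, x$n_edges, x$mode))
  cat(sprintf("  G.E        %.4g\n", x$global_efficiency))
  cat(sprintf("  L.E (mean) %.4g\n", x$local_efficiency$mean))
  cat(sprintf("  C.P.Length %.4g (%d unreachable pairs)\n",
              x$characteristic_path_length$cpl,
              x$characteristic_path_length$n_unreachable_pairs))
  cat(sprintf("  Assort     %s\n",
              if (x$assortativity_undefined) "undefined"
              else sprintf("%.4g", x$assortativity)))
  invisible(x)
}
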