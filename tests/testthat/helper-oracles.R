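# Brute-force oracles for the graph metrics, independent of the package's
# Floyd-Warshall / Brandes implementations: exhaustive enumeration of simple
# paths on tiny graphs.

# all-pairs shortest distances by exhaustive DFS over simple paths
brute_apsp <- function(W) {
  n <- nrow(W)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  for (s in seq_len(n)) {
    dfs <- function(v, dist, visited) {
      if (dist < D[s, v]) D[s, v] <<- dist
      for (u in seq_len(n)) {
        if (!visited[u] && is.finite(W[v, u])) {
          visited[u] <- TRUE
          dfs(u, dist + W[v, u], visited)
          visited[u] <- FALSE
        }
      }
    }
    vis <- rep(FALSE, n)
    vis[s] <- TRUE
    dfs(s, 0, vis)
  }
  D
}

# all shortest paths between s and t: list of node sequences
brute_all_shortest <- function(W, s, t, tol = 1e-9) {
  n <- nrow(W)
  best <- Inf
  paths <- list()
  dfs <- function(v, dist, path, visited) {
    if (dist > best + tol) return()
    if (v == t) {
      if (dist < best - tol) {
        best <<- dist
        paths <<- list(path)
      } else if (abs(dist - best) <= tol) {
        paths[[length(paths) + 1]] <<- path
      }
      return()
    }
    for (u in seq_len(n)) {
      if (!visited[u] && is.finite(W[v, u])) {
        visited[u] <- TRUE
        dfs(u, dist + W[v, u], c(path, u), visited)
        visited[u] <- FALSE
      }
    }
  }
  vis <- rep(FALSE, n)
  vis[s] <- TRUE
  dfs(s, 0, s, vis)
  if (is.infinite(best)) list() else paths
}

brute_betweenness <- function(W) {
  n <- nrow(W)
  bc <- numeric(n)
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      paths <- brute_all_shortest(W, s, t)
      if (length(paths) == 0) next
      through <- numeric(n)
      for (p in paths) {
        interior <- setdiff(p, c(s, t))
        through[interior] <- through[interior] + 1
      }
      bc <- bc + through / length(paths)
    }
  }
  bc
}

brute_efficiency <- function(W) {
  n <- nrow(W)
  if (n < 2) return(0)
  D <- brute_apsp(W)
  inv <- 1 / D
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  sum(inv) / (n * (n - 1))
}

brute_local_efficiency <- function(W) {
  n <- nrow(W)
  sapply(seq_len(n), function(i) {
    nb <- which(is.finite(W[i, ]) & seq_len(n) != i)
    if (length(nb) < 2) return(0)
    brute_efficiency(W[nb, nb, drop = FALSE])
  })
}

brute_assortativity <- function(graph) {
  deg <- graph$nodes$degree
  j <- c(deg[graph$edges$from], deg[graph$edges$to])
  k <- c(deg[graph$edges$to], deg[graph$edges$from])
  suppressWarnings(stats::cor(j, k))
}

# random connected-ish weighted test graph as centerline_graph + dense W
rand_test_graph <- function(n, p = 0.35, weighted = TRUE) {
  repeat {
    A <- matrix(stats::runif(n * n) < p, n, n)
    A[lower.tri(A, diag = TRUE)] <- FALSE
    idx <- which(A, arr.ind = TRUE)
    if (nrow(idx) >= 2) break
  }
  lens <- if (weighted) stats::runif(nrow(idx), 0.5, 2) else rep(1, nrow(idx))
  g <- graph_from_edges(idx, lengths = lens, n_nodes = n)
  W <- matrix(Inf, n, n)
  diag(W) <- 0
  for (e in seq_len(nrow(idx))) {
    W[idx[e, 1], idx[e, 2]] <- lens[e]
    W[idx[e, 2], idx[e, 1]] <- lens[e]
  }
  list(graph = g, W = W)
}

ig_of <- function(graph) {
  ig <- igraph::graph_from_edgelist(
    as.matrix(graph$edges[, c("from", "to")]), directed = FALSE)
  ig <- igraph::add_vertices(ig, max(0, n_nodes(graph) - igraph::vcount(ig)))
  igraph::E(ig)$weight <- graph$edges$length
  ig
}
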