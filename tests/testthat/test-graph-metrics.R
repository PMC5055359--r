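path3 <- function(l1 = 1, l2 = 1) {
  graph_from_edges(rbind(c(1, 2), c(2, 3)), lengths = c(l1, l2), n_nodes = 3)
}

test_that("shortest paths on canonical graphs", {
  g <- path3()
  D <- shortest_path_matrix(g, "binary")
  expect_equal(D[1, 3], 2)
  g2 <- graph_from_edges(rbind(c(1, 2)), n_nodes = 3)
  expect_equal(shortest_path_matrix(g2, "binary")[1, 3], Inf)
})

test_that("efficiency on canonical graphs", {
  k4 <- graph_from_edges(t(combn(4, 2)), n_nodes = 4)
  expect_equal(global_efficiency(k4, "binary"), 1)
  expect_equal(global_efficiency(path3(), "binary"), 5 / 6)
  empty <- graph_from_edges(matrix(integer(), 0, 2), n_nodes = 5)
  expect_equal(global_efficiency(empty, "binary"), 0)

  k3 <- graph_from_edges(rbind(c(1, 2), c(2, 3), c(1, 3)), n_nodes = 3)
  expect_equal(local_efficiency(k3, "binary")$per_node,
               c(N1 = 1, N2 = 1, N3 = 1))
  star <- graph_from_edges(cbind(1, 2:4), n_nodes = 4)
  expect_equal(unname(local_efficiency(star, "binary")$per_node), rep(0, 4))
})

test_that("characteristic path length on canonical graphs", {
  k3 <- graph_from_edges(rbind(c(1, 2), c(2, 3), c(1, 3)), n_nodes = 3)
  expect_equal(characteristic_path_length(k3, "binary")$cpl, 1)
  expect_equal(characteristic_path_length(path3(), "binary")$cpl, 4 / 3)
  expect_equal(characteristic_path_length(path3(2, 3))$cpl, 10 / 3)
})

test_that("betweenness on canonical graphs", {
  b <- betweenness(path3())
  expect_equal(unname(b$per_node), c(0, 1, 0))
  star <- graph_from_edges(cbind(1, 2:6), n_nodes = 6)
  expect_equal(unname(betweenness(star, "binary")$per_node[1]), 1)
  expect_equal(unname(betweenness(star, "binary")$per_node[-1]), rep(0, 5))
})

test_that("assortativity matches the printed minimum tree and handles ties", {
  g <- graph_from_edges(rbind(c(1, 2), c(1, 3), c(1, 4), c(4, 5)),
                        n_nodes = 5)
  expect_equal(round(as.numeric(assortativity(g)), 3), -0.667)
  expect_equal(as.numeric(assortativity(g)), -2 / 3, tolerance = 1e-12)

  ring <- ring_lattice(8, 2)
  a <- assortativity(ring)
  expect_true(is.na(a))
  expect_true(attr(a, "undefined"))
})

test_that("metrics match brute-force enumeration on random graphs", {
  set.seed(101)
  for (k in 1:25) {
    tg <- rand_test_graph(sample(5:9, 1))
    D <- shortest_path_matrix(tg$graph)
    expect_equal(unname(D), brute_apsp(tg$W), tolerance = 1e-9)
    expect_equal(unname(betweenness(tg$graph)$raw), brute_betweenness(tg$W),
                 tolerance = 1e-9)
    expect_equal(unname(local_efficiency(tg$graph)$per_node),
                 brute_local_efficiency(tg$W), tolerance = 1e-9)
    expect_equal(global_efficiency(tg$graph), brute_efficiency(tg$W),
                 tolerance = 1e-9)
    a1 <- as.numeric(assortativity(tg$graph))
    a2 <- brute_assortativity(tg$graph)
    if (is.na(a2)) expect_true(is.na(a1)) else expect_equal(a1, a2,
                                                            tolerance = 1e-9)
  }
})

test_that("GE never decreases when an edge is added", {
  set.seed(55)
  for (k in 1:20) {
    n <- sample(6:15, 1)
    tg <- rand_test_graph(n, p = 0.25, weighted = FALSE)
    g <- tg$graph
    # add one absent edge
    have <- paste(pmin(g$edges$from, g$edges$to),
                  pmax(g$edges$from, g$edges$to))
    all_pairs <- t(combn(n, 2))
    absent <- all_pairs[!paste(all_pairs[, 1], all_pairs[, 2]) %in% have, ,
                        drop = FALSE]
    if (nrow(absent) == 0) next
    pick <- absent[sample.int(nrow(absent), 1), ]
    g2 <- graph_from_edges(rbind(as.matrix(g$edges[, c("from", "to")]),
                                 pick), n_nodes = n)
    expect_gte(global_efficiency(g2, "binary") + 1e-12,
               global_efficiency(g, "binary"))
  }
  # lattice ring vs complete graph
  expect_lt(global_efficiency(ring_lattice(12, 2), "binary"),
            global_efficiency(graph_from_edges(t(combn(12, 2)),
                                               n_nodes = 12), "binary"))
})

test_that("weighted GE scales as 1/s under coordinate scaling", {
  g <- simulate_network(network_config(n_target_branches = 30, seed = 4))
  s <- 3.7
  g2 <- graph_from_edges(as.matrix(g$edges[, c("from", "to")]),
                         coords = as.matrix(g$nodes[, c("x", "y", "z")]) * s,
                         ids = g$nodes$id)
  expect_equal(global_efficiency(g2), global_efficiency(g) / s,
               tolerance = 1e-9)
})

test_that("terminal nodes have zero betweenness and values lie in [0,1]", {
  g <- simulate_network(network_config(n_target_branches = 80, seed = 12))
  b <- betweenness(g)
  expect_true(all(b$per_node >= 0 & b$per_node <= 1))
  expect_true(all(b$per_node[g$nodes$role == "terminal"] == 0))
  expect_identical(sum(b$histogram$count), n_nodes(g))
})
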