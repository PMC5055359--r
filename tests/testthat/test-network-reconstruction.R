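mk_lm <- function(ids, xyz) {
  landmark_set(ids, xyz[, 1], xyz[, 2], xyz[, 3], merge_tol = 0)
}

test_that("build_graph computes Euclidean lengths and assigns roles", {
  lm <- mk_lm(c("A", "B"), rbind(c(0, 0, 0), c(3, 4, 0)))
  g <- build_graph(lm, cbind("A", "B"))
  expect_equal(g$edges$length, 5)
  expect_identical(g$nodes$role, c("terminal", "terminal"))

  # Y: hub connected to 3 tips
  lm <- mk_lm(c("H", "T1", "T2", "T3"),
              rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)))
  g <- build_graph(lm, rbind(c("H", "T1"), c("H", "T2"), c("H", "T3")))
  expect_identical(g$nodes$role,
                   c("furcation", "terminal", "terminal", "terminal"))
})

test_that("build_graph rejects invalid edges by name", {
  lm <- mk_lm(c("A", "B", "C"),
              rbind(c(0, 0, 0), c(1, 0, 0), c(1, 0, 0) + 1))
  expect_error(build_graph(lm, cbind("A", "A")), "self-loop A-A")
  expect_error(build_graph(lm, rbind(c("A", "B"), c("B", "A"))),
               "duplicate edge")
  expect_error(build_graph(lm, cbind("A", "Z")), "unknown landmark")
  lm2 <- landmark_set(c("A", "B"), c(0, 0), c(0, 0), c(0, 0), merge_tol = 0)
  expect_error(build_graph(lm2, cbind("A", "B")), "zero-length")
})

test_that("branches are maximal chains between non-degree-2 nodes", {
  lm <- mk_lm(c("A", "B", "C"),
              rbind(c(0, 0, 0), c(50, 0, 0), c(120, 0, 0)))
  g <- build_graph(lm, rbind(c("A", "B"), c("B", "C")))
  br <- extract_branches(g)
  expect_identical(nrow(br), 1L)
  expect_equal(br$length, 120)

  # Y with three 50 um arms
  lm <- mk_lm(c("H", "T1", "T2", "T3"),
              rbind(c(0, 0, 0), c(50, 0, 0), c(0, 50, 0), c(0, 0, 50)))
  g <- build_graph(lm, rbind(c("H", "T1"), c("H", "T2"), c("H", "T3")))
  br <- extract_branches(g)
  expect_equal(sort(br$length), c(50, 50, 50))
  st <- branch_stats(br)
  expect_equal(st$mean, 50)

  # single branch: mean = median
  one <- branch_stats(extract_branches(build_graph(
    mk_lm(c("A", "B"), rbind(c(0, 0, 0), c(120, 0, 0))), cbind("A", "B"))))
  expect_equal(one$mean, 120)
  expect_equal(one$median, 120)
})

test_that("branch lengths conserve total edge length on random trees", {
  set.seed(11)
  for (k in 1:100) {
    n <- sample(5:40, 1)
    # random tree: attach each node to a random earlier node
    parents <- vapply(2:n, function(i) sample.int(i - 1, 1), integer(1))
    coords <- matrix(stats::runif(3 * n, 0, 200), n)
    g <- graph_from_edges(cbind(parents, 2:n), coords = coords)
    br <- extract_branches(g)
    expect_equal(sum(br$length), sum(g$edges$length), tolerance = 1e-12)
    # endpoints have degree != 2 unless the branch is a closed cycle
    expect_true(all(!br$closed))
  }
})

test_that("branch extraction handles pure cycles as closed branches", {
  theta <- seq(0, 2 * pi, length.out = 7)[-7]
  coords <- cbind(cos(theta), sin(theta), 0) * 30
  g <- graph_from_edges(cbind(1:6, c(2:6, 1)), coords = coords)
  br <- extract_branches(g)
  expect_identical(nrow(br), 1L)
  expect_true(br$closed)
  expect_equal(br$length, sum(g$edges$length))
})

test_that("branch extraction is idempotent under degree-2 contraction", {
  g <- simulate_network(network_config(n_target_branches = 60,
                                       max_segments = 3, seed = 5))
  br <- extract_branches(g)
  # contract: rebuild a graph with one edge per branch, then re-extract
  ids <- strsplit(br$path, ",")
  ends <- t(vapply(ids, function(p) c(p[1], p[length(p)]), character(2)))
  keep <- ends[, 1] != ends[, 2]
  idx <- cbind(match(ends[keep, 1], g$nodes$id),
               match(ends[keep, 2], g$nodes$id))
  g2 <- graph_from_edges(idx, lengths = br$length[keep],
                         n_nodes = n_nodes(g))
  br2 <- extract_branches(g2)
  expect_equal(sort(br2$length), sort(br$length[keep]), tolerance = 1e-9)
})

test_that("furcation angles follow planar geometry and classification", {
  # symmetric planar Y: all angles 120, all beta
  hub <- c(0, 0, 0)
  tips <- rbind(c(1, 0, 0),
                c(cos(2 * pi / 3), sin(2 * pi / 3), 0),
                c(cos(4 * pi / 3), sin(4 * pi / 3), 0)) * 50
  g <- build_graph(mk_lm(c("H", "A", "B", "C"), rbind(hub, tips)),
                   rbind(c("H", "A"), c("H", "B"), c("H", "C")))
  fa <- furcation_angles(g)
  expect_equal(fa$angle, rep(120, 3), tolerance = 1e-9)
  expect_identical(fa$class, rep("beta", 3))

  # parent at 180, daughters at +/-30 degrees: alpha 60, betas 150
  pts <- rbind(c(0, 0, 0), c(-1, 0, 0),
               c(cos(pi / 6), sin(pi / 6), 0),
               c(cos(pi / 6), -sin(pi / 6), 0)) * 40
  pts[1, ] <- 0
  g <- build_graph(mk_lm(c("H", "P", "D1", "D2"), pts),
                   rbind(c("H", "P"), c("H", "D1"), c("H", "D2")))
  fa <- furcation_angles(g)
  expect_equal(sort(fa$angle), c(60, 150, 150), tolerance = 1e-9)
  expect_identical(fa$class[order(fa$angle)], c("alpha", "beta", "beta"))
  # alpha + beta1 + beta2 = 360 for coplanar furcations
  expect_equal(sum(fa$angle), 360, tolerance = 1e-9)
})

test_that("degree-4 nodes emit all C(4,2) angles and 90 degrees is beta", {
  pts <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(-1, 0, 0), c(0, -1, 0)) * 25
  g <- build_graph(mk_lm(c("H", "E", "N", "W", "S"), pts),
                   rbind(c("H", "E"), c("H", "N"), c("H", "W"), c("H", "S")))
  fa <- furcation_angles(g)
  expect_identical(nrow(fa), 6L)
  expect_identical(fa$class[abs(fa$angle - 90) < 1e-9], rep("beta", 4))
})

test_that("angles are invariant under global rigid motion", {
  g <- simulate_network(network_config(n_target_branches = 40, seed = 9))
  fa0 <- furcation_angles(g)
  set.seed(2)
  Q <- random_rotation()
  xyz <- as.matrix(g$nodes[, c("x", "y", "z")]) %*% t(Q)
  xyz <- sweep(xyz, 2, c(13, -40, 7), `+`)
  g2 <- graph_from_edges(as.matrix(g$edges[, c("from", "to")]),
                         coords = xyz, ids = g$nodes$id)
  fa1 <- furcation_angles(g2)
  expect_equal(fa1$angle, fa0$angle, tolerance = 1e-9)
})
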