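degseq <- function(g) sort(g$nodes$degree)

test_that("null surrogates conserve degrees, edges and weight multiset", {
  set.seed(77)
  for (k in 1:15) {
    tg <- rand_test_graph(sample(8:20, 1), p = 0.3)
    g <- tg$graph
    r <- suppressWarnings(randomize_degree_preserving(g))
    l <- suppressWarnings(latticize(g))
    expect_identical(degseq(r), degseq(g))
    expect_identical(degseq(l), degseq(g))
    expect_identical(n_edges(r), n_edges(g))
    expect_identical(n_edges(l), n_edges(g))
    expect_equal(sort(r$edges$length), sort(g$edges$length),
                 tolerance = 1e-12)
    expect_equal(sort(l$edges$length), sort(g$edges$length),
                 tolerance = 1e-12)
  }
})

test_that("graphs admitting no valid swap are returned unchanged", {
  k3 <- graph_from_edges(rbind(c(1, 2), c(2, 3), c(1, 3)), n_nodes = 3)
  expect_warning(r <- randomize_degree_preserving(k3), "no valid")
  expect_identical(as.matrix(r$edges[, c("from", "to")]),
                   as.matrix(k3$edges[, c("from", "to")]))
})

test_that("randomisation actually randomises a path graph", {
  p10 <- graph_from_edges(cbind(1:9, 2:10), n_nodes = 10)
  key <- function(g) paste(sort(paste(pmin(g$edges$from, g$edges$to),
                                      pmax(g$edges$from, g$edges$to))),
                           collapse = ";")
  set.seed(123)
  changed <- sum(vapply(1:200, function(i) {
    key(randomize_degree_preserving(p10)) != key(p10)
  }, logical(1)))
  expect_gt(changed / 200, 0.9)
})

test_that("latticize does not increase the band cost of a ring lattice", {
  rl <- ring_lattice(30, 4)
  ord <- seq_len(30)
  pos <- integer(30); pos[ord] <- seq_len(30)
  cost <- function(g) sum(abs(pos[g$edges$from] - pos[g$edges$to]))
  set.seed(5)
  gl <- latticize(rl, node_order = ord)
  expect_lte(cost(gl), cost(rl))
})

test_that("latticize lowers binary GE of a rewired small-world graph", {
  set.seed(404)
  hits <- 0
  for (k in 1:20) {
    ws <- watts_strogatz(60, 4, 0.5, seed = 9000 + k)
    gl <- latticize(ws)
    hits <- hits + (global_efficiency(gl, "binary") <=
                      global_efficiency(ws, "binary"))
  }
  expect_gte(hits, 18)
})

test_that("small-world verdicts separate regimes on fixed seeds", {
  ws <- watts_strogatz(100, 6, 0.1, seed = 21)
  sw <- small_world_test(ws, n_null = 30, seed = 210)
  expect_true(isTRUE(sw$small_world))
  expect_lt(sw$GE_latt_mean, sw$GE)
  expect_gt(sw$GE_rand_mean, sw$GE)

  ring <- watts_strogatz(100, 6, 0, seed = 1)
  swr <- small_world_test(ring, n_null = 30, seed = 211)
  expect_false(isTRUE(swr$small_world))

  set.seed(212)
  rnd <- randomize_degree_preserving(ws, 20)
  swx <- small_world_test(rnd, n_null = 30, seed = 213)
  expect_false(isTRUE(swx$small_world))
})

test_that("small-world test refuses disconnected graphs, flags tiny ones", {
  two <- graph_from_edges(rbind(c(1, 2), c(3, 4)), n_nodes = 4)
  expect_error(small_world_test(two), "disconnected")
  tiny <- graph_from_edges(rbind(c(1, 2), c(2, 3)), n_nodes = 3)
  expect_identical(small_world_test(tiny)$small_world, "indeterminate")
})

test_that("null ensembles are reproducible under a fixed seed", {
  ws <- watts_strogatz(50, 4, 0.2, seed = 3)
  a <- small_world_test(ws, n_null = 10, seed = 42)
  b <- small_world_test(ws, n_null = 10, seed = 42)
  expect_identical(a[c("GE_rand_mean", "GE_latt_mean", "LE_rand_mean",
                       "LE_latt_mean", "small_world")],
                   b[c("GE_rand_mean", "GE_latt_mean", "LE_rand_mean",
                       "LE_latt_mean", "small_world")])
})
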