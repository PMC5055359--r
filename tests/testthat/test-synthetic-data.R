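test_that("config invariants are enforced", {
  expect_error(network_config(n_target_branches = 0), "positive count")
  expect_error(network_config(branch_length_max = 50), "exceed")
  expect_error(network_config(furcation_prob = 1.5), "0, 1")
  expect_error(network_config(alpha_mean = 95), "0, 90")
  expect_error(network_config(beta_mean = 60), "90, 180")
  expect_error(cell_config("star_like", n_arms = 2), "3 arms")
  expect_error(cell_config("tubular", length = 10, diameter_sagittal = 12),
               "impossible dimensions")
})

test_that("a single-branch network is two nodes and one edge", {
  g <- simulate_network(network_config(n_target_branches = 1, seed = 1))
  expect_identical(n_nodes(g), 2L)
  expect_identical(n_edges(g), 1L)
  expect_true(all(g$nodes$role == "terminal"))
})

test_that("networks are connected and deterministic under a fixed seed", {
  cfg <- network_config(n_target_branches = 80, seed = 31)
  g1 <- simulate_network(cfg)
  g2 <- simulate_network(cfg)
  expect_identical(as.matrix(g1$nodes[, c("x", "y", "z")]),
                   as.matrix(g2$nodes[, c("x", "y", "z")]))
  expect_identical(g1$edges, g2$edges)
  expect_true(is_connected(g1))
  g3 <- simulate_network(network_config(n_target_branches = 80, seed = 32))
  expect_false(identical(as.matrix(g1$nodes[, c("x", "y", "z")]),
                         as.matrix(g3$nodes[, c("x", "y", "z")])))
})

test_that("branch lengths respect the truncation bounds", {
  g <- simulate_network(network_config(n_target_branches = 400, seed = 2))
  br <- extract_branches(g)
  expect_true(all(br$length > 0))
  expect_true(all(br$length <= 300 + 1e-9))
})

test_that("branch lengths pass a KS test against the truncated law", {
  # one-sample KS at alpha = 0.01, n = 1000, on >= 95 of 100 seeds
  mu0 <- purkinet:::truncated_exp_parent_mean(84.6, 300)
  cdf <- function(x) (1 - exp(-x / mu0)) / (1 - exp(-300 / mu0))
  pass <- 0L
  for (sd in 1:100) {
    g <- simulate_network(network_config(n_target_branches = 1000,
                                         seed = 5000 + sd))
    len <- extract_branches(g)$length
    p <- suppressWarnings(stats::ks.test(len, cdf)$p.value)
    pass <- pass + (p > 0.01)
  }
  expect_gte(pass, 95L)
})

test_that("loop closure adds redundant paths while staying valid", {
  g <- simulate_network(network_config(n_target_branches = 60,
                                       loop_prob = 0.5, seed = 8))
  expect_true(is_connected(g))
  expect_gt(n_edges(g), n_nodes(g) - 1)   # at least one cycle
})

test_that("pass-through subdivision conserves branch lengths", {
  g <- simulate_network(network_config(n_target_branches = 150,
                                       max_segments = 3, seed = 6))
  br <- extract_branches(g)
  expect_identical(nrow(br), 150L)
  expect_true(any(g$nodes$role == "pass_through"))
  expect_equal(sum(br$length), sum(g$edges$length), tolerance = 1e-9)
})

test_that("cell meshes are closed genus-0 surfaces with positive measures", {
  for (cfg in list(cell_config("tubular", mesh_resolution = 3),
                   cell_config("star_like", mesh_resolution = 3),
                   cell_config("star_like", n_arms = 5,
                               mesh_resolution = 3))) {
    m <- simulate_cell_mesh(cfg)
    expect_true(is_watertight(m))
    euler <- nrow(m$vertices) - (3 * nrow(m$faces)) / 2 + nrow(m$faces)
    expect_equal(euler, 2)
    expect_gt(surface_area(m), 0)
    expect_gt(enclosed_volume(m), 0)
  }
})

test_that("cell meshes are bit-identical under a fixed seed", {
  a <- simulate_cell_mesh(cell_config("star_like", seed = 5))
  b <- simulate_cell_mesh(cell_config("star_like", seed = 5))
  expect_identical(a$vertices, b$vertices)
  expect_identical(a$faces, b$faces)
})

test_that("unsatisfiable angle draws error after bounded rejections", {
  # a draw law stuck outside (0, 180) can never satisfy triangle closure
  cfg <- list(alpha_mean = -50, alpha_sd = 1e-6,
              beta_mean = 140, beta_sd = 1e-6)
  set.seed(1)
  expect_error(purkinet:::draw_furcation_angles(cfg), "rejections")
})
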