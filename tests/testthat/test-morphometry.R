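test_that("area and volume are exact on cube and tetrahedra", {
  cube <- cube_mesh()
  expect_equal(surface_area(cube), 6)
  expect_equal(enclosed_volume(cube), 1)
  expect_equal(surface_area(regular_tet_mesh(1)), sqrt(3))
  expect_equal(enclosed_volume(unit_tet_mesh()), 1 / 6)
  expect_equal(sv_ratio(6, 1), 6)
})

test_that("sphere estimators converge to the analytic limits", {
  s <- icosphere(10, 4)
  expect_equal(surface_area(s), 4 * pi * 100, tolerance = 0.005)
  expect_equal(enclosed_volume(s), 4 / 3 * pi * 1000, tolerance = 0.005)
})

test_that("capsule volume matches the analytic formula at resolution >= 4", {
  L <- 119.76; d <- 13.76; r <- d / 2
  m <- simulate_cell_mesh(cell_config("tubular", length = L,
                                      diameter_sagittal = d,
                                      mesh_resolution = 4))
  analytic <- pi * r^2 * (L - 2 * r) + 4 / 3 * pi * r^3
  expect_equal(enclosed_volume(m), analytic, tolerance = 0.01)
  dims <- cell_dimensions(m, "tubular")
  expect_equal(dims$length, L, tolerance = 0.01)
  expect_equal(dims$diameter_sagittal, d, tolerance = 0.01)
  expect_true(is.na(dims$diameter_coronal))
})

test_that("area and volume are invariant under rigid motion", {
  set.seed(31)
  m <- simulate_cell_mesh(cell_config("tubular", mesh_resolution = 3))
  a0 <- surface_area(m); v0 <- enclosed_volume(m)
  for (k in 1:3) {
    Q <- random_rotation()
    mr <- rotate_mesh(m, Q, shift = stats::runif(3, -100, 100))
    expect_equal(surface_area(mr), a0, tolerance = 1e-9)
    expect_equal(enclosed_volume(mr), v0, tolerance = 1e-9)
  }
})

test_that("principal-axis dimensions are rotation invariant", {
  m <- simulate_cell_mesh(cell_config("tubular", length = 120,
                                      diameter_sagittal = 14,
                                      mesh_resolution = 4))
  d0 <- cell_dimensions(m, "tubular")
  set.seed(7)
  Q <- random_rotation()
  d1 <- cell_dimensions(rotate_mesh(m, Q, shift = c(5, -3, 11)), "tubular")
  expect_equal(d1$length, d0$length, tolerance = 1e-6)
  expect_equal(d1$diameter_sagittal, d0$diameter_sagittal, tolerance = 1e-6)
})

test_that("isotropic meshes fall back to tie-broken axes with a warning", {
  s <- icosphere(5, 2)
  expect_warning(d <- cell_dimensions(s, "tubular"), "isotropic")
  expect_equal(d$length, 10, tolerance = 0.05)
})

test_that("volume and area scale as s^3 and s^2", {
  m <- simulate_cell_mesh(cell_config("star_like", mesh_resolution = 2))
  s <- 2.5
  big <- trimesh(m$vertices * s, m$faces)
  expect_equal(enclosed_volume(big), enclosed_volume(m) * s^3,
               tolerance = 1e-12)
  expect_equal(surface_area(big), surface_area(m) * s^2, tolerance = 1e-12)
})

test_that("divergence-theorem volume matches the voxel-count oracle", {
  m <- blob_mesh(R = 12, subdivisions = 4)
  vx <- blob_voxel_volume(R = 12, h = 0.31)
  expect_equal(enclosed_volume(m), vx, tolerance = 0.02)
})

test_that("star-like dimensions report span and two diameters", {
  cfg <- cell_config("star_like", length = 63.27, mesh_resolution = 4)
  m <- simulate_cell_mesh(cfg)
  d <- cell_dimensions(m, "star_like")
  expect_equal(d$length, 63.27, tolerance = 0.1)
  expect_true(d$diameter_sagittal > d$diameter_coronal)
  chord <- cell_dimensions(m, "star_like", method = "chord")
  expect_gte(chord$length + 1e-9, d$length)
})

test_that("cell_morphometry ties the pieces together", {
  m <- simulate_cell_mesh(cell_config("tubular", mesh_resolution = 3))
  cm <- cell_morphometry(m, "tubular")
  expect_equal(cm$sv_ratio, cm$surface_area / cm$volume, tolerance = 1e-9)
  expect_true(all(unlist(cm[c("length", "diameter_sagittal",
                              "surface_area", "volume", "sv_ratio")]) > 0))
})

test_that("degenerate faces are tallied, open meshes rejected for volume", {
  cube <- cube_mesh()
  v <- rbind(cube$vertices, cube$vertices[8, ])
  # replace a face with a zero-area sliver (vertex 9 duplicates vertex 8)
  f <- cube$faces
  f[1, ] <- c(8L, 9L, 8L)
  m <- structure(list(vertices = v, faces = f), class = "trimesh")
  expect_warning(surface_area(m, check = FALSE), "degenerate")
  open_mesh <- structure(list(vertices = cube$vertices,
                              faces = cube$faces[-1, ]), class = "trimesh")
  expect_error(enclosed_volume(open_mesh), "closed")
})
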