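# Canonical closed meshes with known area/volume, built in code.

cube_mesh <- function(side = 1) {
  v <- as.matrix(expand.grid(c(0, side), c(0, side), c(0, side)))
  dimnames(v) <- NULL
  f <- rbind(
    c(1, 3, 4), c(1, 4, 2),   # z = 0
    c(5, 6, 8), c(5, 8, 7),   # z = side
    c(1, 2, 6), c(1, 6, 5),   # y = 0
    c(3, 7, 8), c(3, 8, 4),   # y = side
    c(1, 5, 7), c(1, 7, 3),   # x = 0
    c(2, 4, 8), c(2, 8, 6))   # x = side
  trimesh(v, f)
}

# regular tetrahedron with edge length `edge`
regular_tet_mesh <- function(edge = 1) {
  v <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  v <- v / sqrt(8) * edge      # edge length of this embedding is 2*sqrt(2)
  f <- rbind(c(1, 3, 2), c(1, 2, 4), c(1, 4, 3), c(2, 3, 4))
  trimesh(v, f)
}

# unit tetrahedron (0,0,0),(1,0,0),(0,1,0),(0,0,1): volume 1/6
unit_tet_mesh <- function() {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  f <- rbind(c(1, 3, 2), c(1, 2, 4), c(1, 4, 3), c(2, 3, 4))
  trimesh(v, f)
}

# smooth star-shaped "blob": radius as a deterministic function of direction
blob_radius <- function(dirs, R = 12) {
  th <- acos(pmin(1, pmax(-1, dirs[, 3])))
  ph <- atan2(dirs[, 2], dirs[, 1])
  R * (1 + 0.18 * sin(3 * th) * cos(2 * ph) + 0.12 * cos(2 * th) * sin(3 * ph))
}

blob_mesh <- function(R = 12, subdivisions = 4) {
  s <- icosphere(1, subdivisions)
  r <- blob_radius(s$vertices, R)
  trimesh(s$vertices * r, s$faces)
}

# voxel-count volume oracle: count grid centres strictly inside the blob
blob_voxel_volume <- function(R = 12, h = 0.31) {
  lim <- R * 1.4
  g <- seq(-lim, lim, by = h)
  vol <- 0
  for (z in g) {   # slice-wise to bound memory
    xy <- as.matrix(expand.grid(g, g))
    p <- cbind(xy, z)
    rr <- sqrt(rowSums(p^2))
    inside <- rr > 0
    d <- p[inside, , drop = FALSE] / rr[inside]
    vol <- vol + sum(rr[inside] < blob_radius(d, R))
  }
  vol * h^3
}

# random 3D rotation matrix (uniform via QR of gaussian matrix)
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3))
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

rotate_mesh <- function(mesh, Q, shift = c(0, 0, 0)) {
  trimesh(sweep(mesh$vertices %*% t(Q), 2, shift, `+`), mesh$faces)
}
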