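#' Configuration for synthetic Purkinje cell meshes
#'
#' Dimension defaults follow the two measured cell populations: tubular
#' cells about 119.76 um long with a 13.76 um diameter, and star-like cells
#' spanning about 63.27 um with a 19.70 um sagittal and 6.79 um coronal
#' diameter.
#'
#' @param kind `"tubular"` or `"star_like"`.
#' @param length cell length in micrometres (tubular: capsule end-to-end;
#'   star-like: longest arm-tip-to-arm-tip span).
#' @param diameter_sagittal transverse diameter, um (tubular: the capsule
#'   diameter; star-like: hub width).
#' @param diameter_coronal star-like only: flattened thickness, um.
#' @param n_arms star-like only: number of arms (>= 3).
#' @param mesh_resolution subdivision level controlling tessellation
#'   density.
#' @param seed integer seed (controls the slight star-arm irregularity).
#' @return An object of class `synthetic_cell_config`.
#' @export
cell_config <- function(kind = c("tubular", "star_like"),
                        length = NULL,
                        diameter_sagittal = NULL,
                        diameter_coronal = NULL,
                        n_arms = 3,
                        mesh_resolution = 4,
                        seed = 1L) {
  kind <- match.arg(kind)
  if (is.null(length)) length <- if (kind == "tubular") 119.76 else 63.27
  if (is.null(diameter_sagittal)) {
    diameter_sagittal <- if (kind == "tubular") 13.76 else 19.70
  }
  if (kind == "star_like" && is.null(diameter_coronal)) diameter_coronal <- 6.79
  stopifnot(length > 0, diameter_sagittal > 0, mesh_resolution >= 1)
  if (diameter_sagittal >= length) {
    stopf("impossible dimensions: diameter (%.3g) must be smaller than length (%.3g)",
          diameter_sagittal, length)
  }
  if (kind == "star_like") {
    if (!is_count(n_arms) || n_arms < 3) {
      stopf("star-like cells need at least 3 arms (got %s)", n_arms)
    }
    if (is.null(diameter_coronal) || diameter_coronal <= 0) {
      stopf("star-like cells need diameter_coronal > 0")
    }
  } else {
    diameter_coronal <- NA_real_
  }
  cfg <- list(kind = kind, length = length,
              diameter_sagittal = diameter_sagittal,
              diameter_coronal = diameter_coronal,
              n_arms = as.integer(n_arms),
              mesh_resolution = as.integer(mesh_resolution),
              seed = as.integer(seed))
  class(cfg) <- "synthetic_cell_config"
  cfg
}

#' Simulate a parametric cell mesh
#'
#' Stand-in for manual 3D segmentation: generates a closed, consistently
#' oriented, self-intersection-free triangle mesh of a single cell.
#' Tubular cells are capsules (cylinder with hemispherical caps) aligned
#' with the x axis; star-like cells are flattened hubs with `n_arms`
#' tapering arms in the xy plane, built as a star-shaped radial surface
#' (so watertightness is guaranteed by construction). Deterministic under
#' the configured seed.
#'
#' @param config a [cell_config()].
#' @return A [trimesh].
#' @examples
#' m <- simulate_cell_mesh(cell_config("tubular", mesh_resolution = 3))
#' @export
simulate_cell_mesh <- function(config) {
  stopifnot(inherits(config, "synthetic_cell_config"))
  if (config$kind == "tubular") {
    capsule_mesh(config$length, config$diameter_sagittal / 2,
                 config$mesh_resolution)
  } else {
    star_mesh(config)
  }
}

# Capsule: cylinder of length L - 2r capped by hemispheres; total extent L
# along x. Resolution k gives 2^(k+2) vertices around the circumference.
capsule_mesh <- function(L, r, resolution) {
  if (L <= 2 * r) stopf("capsule needs length > diameter")
  n_circ <- 2^(resolution + 2)
  n_lat <- 2^resolution          # rings per hemisphere
  n_ax <- max(2, 2^(resolution - 1))  # rings along the cylinder
  half <- L / 2 - r
  phi <- seq(0, 2 * pi, length.out = n_circ + 1)[-(n_circ + 1)]
  rows <- list()
  # south pole cap (x = -L/2), rings from pole to equator
  rows[[1]] <- matrix(c(-L / 2, 0, 0), 1, 3)
  for (i in seq_len(n_lat)) {
    th <- i / n_lat * pi / 2
    rr <- r * sin(th)
    x <- -half - r * cos(th)
    rows[[length(rows) + 1]] <- cbind(x, rr * cos(phi), rr * sin(phi))
  }
  for (i in seq_len(n_ax - 1)) {
    x <- -half + 2 * half * i / n_ax
    rows[[length(rows) + 1]] <- cbind(x, r * cos(phi), r * sin(phi))
  }
  for (i in n_lat:1) {
    th <- i / n_lat * pi / 2
    rr <- r * sin(th)
    x <- half + r * cos(th)
    rows[[length(rows) + 1]] <- cbind(x, rr * cos(phi), rr * sin(phi))
  }
  rows[[length(rows) + 1]] <- matrix(c(L / 2, 0, 0), 1, 3)
  lathe_mesh(rows, n_circ)
}

# Triangulate a stack of rings (first and last entries are single apex
# points) into a closed surface with outward orientation.
lathe_mesh <- function(rows, n_circ) {
  verts <- do.call(rbind, rows)
  sizes <- vapply(rows, nrow, integer(1))
  offset <- cumsum(c(0, utils::head(sizes, -1)))
  n_rows <- length(rows)
  faces <- list()
  ring <- function(i, j) offset[i] + (j - 1L) %% n_circ + 1L
  # apex fans
  for (j in seq_len(n_circ)) {
    faces[[length(faces) + 1]] <- c(1L, ring(2, j + 1), ring(2, j))
  }
  for (i in 2:(n_rows - 2)) {
    for (j in seq_len(n_circ)) {
      a <- ring(i, j); b <- ring(i, j + 1)
      cc <- ring(i + 1, j); d <- ring(i + 1, j + 1)
      faces[[length(faces) + 1]] <- c(a, b, d)
      faces[[length(faces) + 1]] <- c(a, d, cc)
    }
  }
  apex2 <- offset[n_rows] + 1L
  for (j in seq_len(n_circ)) {
    faces[[length(faces) + 1]] <- c(apex2, ring(n_rows - 1, j),
                                    ring(n_rows - 1, j + 1))
  }
  trimesh(verts, do.call(rbind, faces))
}

# Star-like cell: a star-shaped surface r(theta, phi) over a UV sphere.
# In-plane radius swells from the hub radius to the arm-tip radius under a
# sharpened cosine lobe per arm (with seeded per-arm length jitter breaking
# the n-fold symmetry, as real cells do); the z semi-axis is the flattened
# coronal half-thickness, tapering with the local in-plane radius so arms
# are thinner than the hub.
star_mesh <- function(cfg) {
  n_circ <- 2^(cfg$mesh_resolution + 3)
  n_lat <- 2^(cfg$mesh_resolution + 1)
  hub_r <- cfg$diameter_sagittal / 2
  n <- cfg$n_arms
  # arm-tip radius such that the widest tip-to-tip span equals `length`:
  # adjacent azimuth gap between arms is 2*pi/n; the longest chord spans
  # floor(n/2) gaps.
  gap <- 2 * pi / n
  span_angle <- gap * floor(n / 2)
  tip_r <- cfg$length / (2 * sin(span_angle / 2))
  arm_phi <- (0:(n - 1)) * gap
  jitter <- with_seed(cfg$seed, stats::runif(n, 0.92, 1.0))
  # the two arms realising the longest span keep jitter 1 so the span is exact
  widest <- c(1L, 1L + floor(n / 2))
  jitter[widest] <- 1.0
  phi <- seq(0, 2 * pi, length.out = n_circ + 1)[-(n_circ + 1)]
  lobe <- function(ph) {
    m <- 0
    for (k in seq_len(n)) {
      dk <- cos(ph - arm_phi[k])
      m <- pmax(m, jitter[k] * pmax(0, dk)^8)
    }
    m
  }
  R_phi <- hub_r + (tip_r - hub_r) * lobe(phi)
  cz <- cfg$diameter_coronal / 2
  rows <- list()
  rows[[1]] <- matrix(c(0, 0, cz), 1, 3)
  for (i in seq_len(n_lat - 1)) {
    th <- i / n_lat * pi
    rr <- R_phi * sin(th)
    z <- cz * cos(th) * (0.25 + 0.75 * hub_r / pmax(R_phi, hub_r))
    rows[[length(rows) + 1]] <- cbind(rr * cos(phi), rr * sin(phi), z)
  }
  rows[[length(rows) + 1]] <- matrix(c(0, 0, -cz), 1, 3)
  m <- lathe_mesh(rows, n_circ)
  # lathe_mesh orients for x-axis lathes; orientation fixed in trimesh()
  m
}
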