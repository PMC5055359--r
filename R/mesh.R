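#' Closed triangle meshes
#'
#' A `trimesh` is a closed, consistently oriented triangle surface of a
#' single segmented cell: an `n x 3` vertex matrix (micrometres) and an
#' `m x 3` integer face matrix of 1-based vertex indices. Construction
#' validates watertightness (every undirected edge shared by exactly two
#' faces) and orientation consistency (each edge traversed once in each
#' direction), and flips all faces if the signed volume is negative so that
#' normals point outward.
#'
#' @param vertices numeric matrix with 3 columns.
#' @param faces integer matrix with 3 columns, 1-based indices.
#' @param validate check watertightness/orientation (default `TRUE`).
#' @return An object of class `trimesh`.
#' @export
trimesh <- function(vertices, faces, validate = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3 || ncol(faces) != 3) {
    stopf("vertices and faces must have 3 columns")
  }
  if (nrow(faces) > 0 && (min(faces) < 1 || max(faces) > nrow(vertices))) {
    stopf("face indices out of range 1..%d", nrow(vertices))
  }
  m <- structure(list(vertices = vertices, faces = faces), class = "trimesh")
  if (validate) {
    chk <- mesh_check(m)
    if (chk$n_boundary > 0) {
      stopf("mesh is not closed: %d boundary edges", chk$n_boundary)
    }
    if (chk$n_nonmanifold > 0) {
      stopf("mesh is non-manifold: %d edges shared by more than two faces",
            chk$n_nonmanifold)
    }
    if (!chk$oriented) stopf("mesh faces are not consistently oriented")
    if (enclosed_volume(m, check = FALSE) < 0) {
      m$faces <- m$faces[, c(1, 3, 2), drop = FALSE]
    }
  }
  m
}

#' @export
print.trimesh <- function(x, ...) {
  cat(sprintf("<trimesh> %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

# Edge bookkeeping: counts of boundary (1 face) and non-manifold (>2 faces)
# undirected edges, plus directed-edge orientation consistency.
mesh_check <- function(mesh) {
  f <- mesh$faces
  he_from <- c(f[, 1], f[, 2], f[, 3])
  he_to   <- c(f[, 2], f[, 3], f[, 1])
  a <- pmin(he_from, he_to)
  b <- pmax(he_from, he_to)
  key <- paste(a, b)
  tab <- table(key)
  n_boundary <- sum(tab == 1)
  n_nonmanifold <- sum(tab > 2)
  # consistently oriented: every directed half-edge occurs exactly once
  dkey <- paste(he_from, he_to)
  oriented <- !anyDuplicated(dkey) && n_boundary == 0 && n_nonmanifold == 0
  list(n_boundary = n_boundary, n_nonmanifold = n_nonmanifold,
       oriented = oriented)
}

#' Test whether a mesh is watertight
#'
#' @param mesh a [trimesh].
#' @return `TRUE` if every edge is shared by exactly two faces.
#' @export
is_watertight <- function(mesh) {
  chk <- mesh_check(mesh)
  chk$n_boundary == 0 && chk$n_nonmanifold == 0
}

#' Geodesic icosphere
#'
#' Subdivided icosahedron projected onto a sphere; the standard near-uniform
#' sphere tessellation used as a building block for synthetic cells and for
#' convergence checks of surface/volume estimators.
#'
#' @param radius sphere radius in micrometres.
#' @param subdivisions number of 4-to-1 triangle subdivisions (0 gives the
#'   icosahedron, 20 faces; each level quadruples the face count).
#' @param center sphere centre (length-3 numeric).
#' @return A [trimesh].
#' @export
icosphere <- function(radius = 1, subdivisions = 3, center = c(0, 0, 0)) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    midcache <- new.env(hash = TRUE)
    nv <- nrow(v)
    vlist <- vector("list", 4 * nrow(f))
    newf <- matrix(0L, 4 * nrow(f), 3)
    extra <- list()
    midpoint <- function(i, j) {
      k <- paste(min(i, j), max(i, j))
      hit <- midcache[[k]]
      if (!is.null(hit)) return(hit)
      p <- unitize(v[i, ] + v[j, ])
      extra[[length(extra) + 1]] <<- p
      idx <- nv + length(extra)
      midcache[[k]] <- idx
      idx
    }
    for (t in seq_len(nrow(f))) {
      a <- f[t, 1]; b <- f[t, 2]; cc <- f[t, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
      newf[4 * t - 3, ] <- c(a, ab, ca)
      newf[4 * t - 2, ] <- c(b, bc, ab)
      newf[4 * t - 1, ] <- c(cc, ca, bc)
      newf[4 * t, ]     <- c(ab, bc, ca)
    }
    v <- rbind(v, do.call(rbind, extra))
    f <- newf
  }
  verts <- sweep(v * radius, 2, center, `+`)
  trimesh(verts, f)
}

# ---------------------------------------------------------------------------
# Mesh file I/O: PLY (ascii + binary little-endian), OBJ, STL (ascii).
# No installed R package reads these formats, so the readers/writers live
# here; they cover exactly the subset the pipeline emits.

#' Read a triangle mesh from PLY, OBJ or STL
#'
#' The format is inferred from the file extension. PLY may be ascii or
#' binary little-endian; OBJ faces are triangulated by fanning; STL input
#' (ascii) duplicates vertices per facet, which are merged on read by exact
#' coordinate hashing. Open or non-manifold surfaces are rejected with the
#' boundary-edge count in the error message.
#'
#' @param path mesh file.
#' @return A [trimesh].
#' @export
read_mesh <- function(path) {
  if (!file.exists(path)) stopf("mesh file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         ply = read_ply(path),
         obj = read_obj(path),
         stl = read_stl(path),
         stopf("unsupported mesh format '.%s' (use PLY, OBJ or STL)", ext))
}

#' Write a triangle mesh
#'
#' @param mesh a [trimesh].
#' @param path output file.
#' @param format one of `"ply"` (binary little-endian, the default),
#'   `"ply_ascii"`, `"obj"`, `"stl"` (ascii). Defaults to the extension of
#'   `path` when omitted.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, format = NULL) {
  stopifnot(inherits(mesh, "trimesh"))
  if (is.null(format)) format <- tolower(tools::file_ext(path))
  format <- match.arg(format, c("ply", "ply_ascii", "obj", "stl"))
  switch(format,
         ply = write_ply(mesh, path, binary = TRUE),
         ply_ascii = write_ply(mesh, path, binary = FALSE),
         obj = write_obj(mesh, path),
         stl = write_stl(mesh, path))
  invisible(path)
}

write_ply <- function(mesh, path, binary = TRUE) {
  nv <- nrow(mesh$vertices); nf <- nrow(mesh$faces)
  header <- c(
    "ply",
    if (binary) "format binary_little_endian 1.0" else "format ascii 1.0",
    "comment purkinet mesh",
    sprintf("element vertex %d", nv),
    "property double x", "property double y", "property double z",
    sprintf("element face %d", nf),
    "property list uchar int vertex_indices",
    "end_header")
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(header, con, sep = "\n")
    writeBin(as.vector(t(mesh$vertices)), con, size = 8, endian = "little")
    fm <- t(cbind(3L, mesh$faces - 1L))
    for (i in seq_len(nf)) {
      writeBin(as.raw(3L), con)
      writeBin(as.integer(mesh$faces[i, ] - 1L), con, size = 4,
               endian = "little")
    }
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(header, con)
    writeLines(sprintf("%.9g %.9g %.9g", mesh$vertices[, 1],
                       mesh$vertices[, 2], mesh$vertices[, 3]), con)
    writeLines(sprintf("3 %d %d %d", mesh$faces[, 1] - 1L,
                       mesh$faces[, 2] - 1L, mesh$faces[, 3] - 1L), con)
  }
  invisible(path)
}

read_ply <- function(path) {
  raw_all <- readBin(path, "raw", file.info(path)$size)
  marker <- charToRaw("end_header\n")
  hit <- which(vapply(seq_len(length(raw_all) - length(marker) + 1),
                      function(i) all(raw_all[i:(i + length(marker) - 1)] ==
                                        marker), logical(1)))[1]
  if (is.na(hit)) stopf("no end_header in PLY file %s", path)
  body_start <- hit + length(marker)
  header <- strsplit(rawToChar(raw_all[seq_len(body_start - 1)]),
                     "\n")[[1]]
  header <- sub("\r$", "", header)
  fmt <- grep("^format ", header, value = TRUE)
  binary <- grepl("binary_little_endian", fmt)
  if (!binary && !grepl("ascii", fmt)) {
    stopf("unsupported PLY format in %s: %s", path, fmt)
  }
  nv <- as.integer(sub("element vertex ", "",
                       grep("^element vertex", header, value = TRUE)))
  nf <- as.integer(sub("element face ", "",
                       grep("^element face", header, value = TRUE)))
  vtypes <- character()   # property storage types, in declaration order
  vnames <- character()   # property names (x, y, z, ...)
  in_vertex <- FALSE
  for (ln in header) {
    if (grepl("^element vertex", ln)) in_vertex <- TRUE
    else if (grepl("^element", ln)) in_vertex <- FALSE
    else if (in_vertex && grepl("^property", ln)) {
      tok <- strsplit(trimws(ln), "\\s+")[[1]]
      vtypes <- c(vtypes, tok[2])
      vnames <- c(vnames, tok[3])
    }
  }
  psize <- c(float = 4L, double = 8L, uchar = 1L, int = 4L, uint = 4L)
  if (binary) {
    payload <- raw_all[body_start:length(raw_all)]
    sizes <- psize[vtypes]
    stride <- sum(sizes)
    if (length(payload) < nv * stride) stopf("truncated PLY payload in %s", path)
    verts <- matrix(NA_real_, nv, length(vtypes))
    off <- 0L
    for (i in seq_len(nv)) {
      for (j in seq_along(vtypes)) {
        verts[i, j] <- readBin(payload[(off + 1):(off + sizes[j])], "double",
                               1, size = sizes[j], endian = "little")
        off <- off + sizes[j]
      }
    }
    faces <- matrix(0L, nf, 3)
    for (i in seq_len(nf)) {
      cnt <- as.integer(payload[off + 1L])
      off <- off + 1L
      if (cnt != 3) stopf("PLY face %d has %d vertices; only triangles supported", i, cnt)
      faces[i, ] <- readBin(payload[(off + 1):(off + 12L)], "integer", 3,
                            size = 4, endian = "little") + 1L
      off <- off + 12L
    }
  } else {
    body <- header_body_lines(raw_all, body_start)
    vl <- strsplit(trimws(body[seq_len(nv)]), "\\s+")
    verts <- t(vapply(vl, function(p) as.numeric(p[seq_along(vtypes)]),
                      numeric(length(vtypes))))
    fl <- strsplit(trimws(body[nv + seq_len(nf)]), "\\s+")
    faces <- t(vapply(fl, function(p) {
      if (as.integer(p[1]) != 3) stopf("non-triangle face in %s", path)
      as.integer(p[2:4]) + 1L
    }, integer(3)))
  }
  xyz <- match(c("x", "y", "z"), vnames)
  if (any(is.na(xyz))) stopf("PLY file %s lacks x/y/z vertex properties", path)
  trimesh(verts[, xyz, drop = FALSE], faces)
}

header_body_lines <- function(raw_all, body_start) {
  body <- strsplit(rawToChar(raw_all[body_start:length(raw_all)]),
                   "\n")[[1]]
  body[nzchar(trimws(body))]
}

write_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# purkinet mesh", con)
  writeLines(sprintf("v %.9g %.9g %.9g", mesh$vertices[, 1],
                     mesh$vertices[, 2], mesh$vertices[, 3]), con)
  writeLines(sprintf("f %d %d %d", mesh$faces[, 1], mesh$faces[, 2],
                     mesh$faces[, 3]), con)
  invisible(path)
}

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^v ", lines, value = TRUE)
  fl <- grep("^f ", lines, value = TRUE)
  verts <- t(vapply(strsplit(trimws(sub("^v", "", vl)), "\\s+"),
                    function(p) as.numeric(p[1:3]), numeric(3)))
  faces <- do.call(rbind, lapply(strsplit(trimws(sub("^f", "", fl)), "\\s+"),
    function(p) {
      idx <- as.integer(sub("/.*", "", p))
      if (length(idx) < 3) stopf("OBJ face with fewer than 3 vertices")
      # fan-triangulate polygons
      t(vapply(seq_len(length(idx) - 2),
               function(k) c(idx[1], idx[k + 1], idx[k + 2]), integer(3)))
    }))
  trimesh(verts, faces)
}

write_stl <- function(mesh, path) {
  v <- mesh$vertices; f <- mesh$faces
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid purkinet", con)
  for (i in seq_len(nrow(f))) {
    p1 <- v[f[i, 1], ]; p2 <- v[f[i, 2], ]; p3 <- v[f[i, 3], ]
    n <- pracma_cross(p2 - p1, p3 - p1)
    nn <- vnorm(n)
    if (nn > 0) n <- n / nn
    writeLines(c(sprintf("  facet normal %.9g %.9g %.9g", n[1], n[2], n[3]),
                 "    outer loop",
                 sprintf("      vertex %.9g %.9g %.9g", c(p1[1], p2[1], p3[1]),
                         c(p1[2], p2[2], p3[2]), c(p1[3], p2[3], p3[3])),
                 "    endloop", "  endfacet"), con)
  }
  writeLines("endsolid purkinet", con)
  invisible(path)
}

read_stl <- function(path) {
  head <- readBin(path, "raw", 5)
  if (!identical(rawToChar(head), "solid")) {
    stopf("binary STL not supported: %s (write ascii STL)", path)
  }
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (length(vl) %% 3 != 0) stopf("malformed STL: vertex count not divisible by 3")
  coords <- t(vapply(strsplit(trimws(sub("\\s*vertex", "", vl)), "\\s+"),
                     function(p) as.numeric(p[1:3]), numeric(3)))
  # merge duplicated vertices by exact coordinate hashing
  key <- paste(coords[, 1], coords[, 2], coords[, 3])
  uidx <- !duplicated(key)
  verts <- coords[uidx, , drop = FALSE]
  lookup <- match(key, key[uidx])
  faces <- matrix(lookup, ncol = 3, byrow = TRUE)
  trimesh(verts, faces)
}
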