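#' Labelled 3D landmark sets
#'
#' A `landmark_set` holds the manually (or synthetically) placed waypoints of
#' a Purkinje centreline reconstruction: one labelled 3D point per landmark,
#' coordinates in micrometres, in either the RAS or LPS anatomical frame.
#'
#' @param id character vector of unique landmark identifiers.
#' @param x,y,z numeric coordinates in micrometres.
#' @param frame coordinate frame, `"RAS"` or `"LPS"`.
#' @param stack_id identifier of the originating image stack.
#' @param merge_tol minimum allowed distance between two landmarks in
#'   micrometres. The default, 0.31, is one confocal voxel; two landmarks
#'   closer than this are indistinguishable at acquisition resolution and are
#'   rejected.
#' @return An object of class `landmark_set`: a data frame with columns
#'   `id`, `x`, `y`, `z` and attributes `frame` and `stack_id`.
#' @examples
#' lm <- landmark_set(c("F1", "F2"), x = c(0, 3), y = c(0, 4), z = c(0, 0))
#' @export
landmark_set <- function(id, x, y, z, frame = c("RAS", "LPS"),
                         stack_id = "stack", merge_tol = 0.31) {
  frame <- match.arg(frame)
  id <- as.character(id)
  if (anyDuplicated(id)) {
    stopf("duplicate landmark id: %s",
          paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  xyz <- cbind(as.numeric(x), as.numeric(y), as.numeric(z))
  if (length(id) != nrow(xyz)) stopf("id and coordinates differ in length")
  if (!all(is.finite(xyz))) stopf("non-finite landmark coordinates")
  if (merge_tol > 0 && nrow(xyz) > 1) {
    d <- as.matrix(stats::dist(xyz))
    diag(d) <- Inf
    hit <- which(d < merge_tol, arr.ind = TRUE)
    if (nrow(hit) > 0) {
      i <- hit[1, 1]; j <- hit[1, 2]
      stopf("landmarks %s and %s are closer than the merge tolerance (%.3g um)",
            id[i], id[j], merge_tol)
    }
  }
  out <- data.frame(id = id, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                    stringsAsFactors = FALSE)
  attr(out, "frame") <- frame
  attr(out, "stack_id") <- stack_id
  class(out) <- c("landmark_set", "data.frame")
  out
}

#' @export
print.landmark_set <- function(x, ...) {
  cat(sprintf("<landmark_set> %d points, frame %s, stack %s\n",
              nrow(x), attr(x, "frame"), attr(x, "stack_id")))
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat(sprintf("... and %d more\n", nrow(x) - 6))
  invisible(x)
}

#' Convert a landmark set between the RAS and LPS frames
#'
#' The two frames differ by the sign of the first two axes, so conversion
#' negates `x` and `y`; applying it twice is the identity.
#'
#' @param landmarks a [landmark_set].
#' @param to target frame, `"RAS"` or `"LPS"`.
#' @return The converted `landmark_set`.
#' @export
convert_frame <- function(landmarks, to = c("RAS", "LPS")) {
  to <- match.arg(to)
  stopifnot(inherits(landmarks, "landmark_set"))
  if (attr(landmarks, "frame") == to) return(landmarks)
  landmarks$x <- -landmarks$x
  landmarks$y <- -landmarks$y
  attr(landmarks, "frame") <- to
  landmarks
}

#' Read landmarks from a fiducial CSV file
#'
#' The dialect is the widely used fiducial CSV: comma-separated columns
#' `id,x,y,z[,label]`, one landmark per row, `#`-prefixed comment lines
#' ignored. Coordinates are micrometres. A comment line of the form
#' `# CoordinateSystem = RAS` (or `LPS`) declares the frame; LPS input is
#' converted to RAS on read by negating `x` and `y`.
#'
#' @param path file to read.
#' @param frame_override optional frame (`"RAS"`/`"LPS"`) taking precedence
#'   over (or supplying, when absent) the file's header declaration.
#' @param merge_tol minimum landmark separation in micrometres (see
#'   [landmark_set]).
#' @param stack_id stack identifier attached to the result; defaults to the
#'   file name.
#' @return A [landmark_set] in the RAS frame.
#' @export
read_landmarks <- function(path, frame_override = NULL, merge_tol = 0.31,
                           stack_id = NULL) {
  if (!file.exists(path)) stopf("landmark file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  frame <- NULL
  for (ln in grep("^#", lines, value = TRUE)) {
    m <- regmatches(ln, regexec("CoordinateSystem\\s*=\\s*([A-Za-z]+)", ln))[[1]]
    if (length(m) == 2) frame <- toupper(m[2])
  }
  if (!is.null(frame_override)) frame <- toupper(frame_override)
  if (is.null(frame)) stopf("no coordinate frame declared in %s and no frame_override given", path)
  if (!frame %in% c("RAS", "LPS")) stopf("unknown coordinate frame '%s'", frame)

  body <- lines[!grepl("^\\s*(#|$)", lines)]
  # tolerate a non-comment header row
  if (length(body) > 0 && grepl("^\\s*id\\s*,", body[1], ignore.case = TRUE)) {
    body <- body[-1]
  }
  if (length(body) == 0) stopf("no landmark rows in %s", path)
  parts <- strsplit(body, ",")
  ids <- character(length(parts))
  xyz <- matrix(NA_real_, length(parts), 3)
  for (i in seq_along(parts)) {
    p <- trimws(parts[[i]])
    if (length(p) < 4) stopf("line %d of %s: expected id,x,y,z", i, path)
    ids[i] <- p[1]
    co <- suppressWarnings(as.numeric(p[2:4]))
    if (any(is.na(co))) {
      stopf("line %d of %s: non-numeric coordinate for landmark '%s'",
            i, path, p[1])
    }
    xyz[i, ] <- co
  }
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])[1]
    stopf("duplicate landmark id '%s' in %s", dup, path)
  }
  lm <- landmark_set(ids, xyz[, 1], xyz[, 2], xyz[, 3], frame = frame,
                     stack_id = if (is.null(stack_id)) basename(path) else stack_id,
                     merge_tol = merge_tol)
  convert_frame(lm, "RAS")
}

#' Write landmarks to a fiducial CSV file
#'
#' @param landmarks a [landmark_set].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(landmarks, path) {
  stopifnot(inherits(landmarks, "landmark_set"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# CoordinateSystem = %s", attr(landmarks, "frame")),
               sprintf("# stack = %s", attr(landmarks, "stack_id")),
               "id,x,y,z"), con)
  writeLines(sprintf("%s,%.9g,%.9g,%.9g",
                     landmarks$id, landmarks$x, landmarks$y, landmarks$z), con)
  invisible(path)
}

#' Read or write an edge list
#'
#' Edge connectivity between landmarks is stored separately from the fiducial
#' CSV (the landmark export itself carries no topology): a two-column
#' tab-separated file of landmark ids, one undirected edge per row,
#' `#` comments ignored.
#'
#' @param path file to read or write.
#' @return `read_edge_list()` returns a two-column character matrix
#'   (`from`, `to`).
#' @export
read_edge_list <- function(path) {
  if (!file.exists(path)) stopf("edge list not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  parts <- strsplit(lines, "\t|,| +")
  bad <- which(vapply(parts, length, 1L) < 2)
  if (length(bad)) stopf("edge list %s line %d: expected two ids", path, bad[1])
  m <- t(vapply(parts, function(p) p[1:2], character(2)))
  colnames(m) <- c("from", "to")
  m
}

#' @param edges a two-column matrix or data frame of landmark ids.
#' @rdname read_edge_list
#' @export
write_edge_list <- function(edges, path) {
  edges <- as.matrix(edges)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# from\tto", con)
  writeLines(paste(edges[, 1], edges[, 2], sep = "\t"), con)
  invisible(path)
}
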