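# Triangle-mesh container and minimal ASCII STL / OBJ io for implant surfaces.

#' Articulating implant surface
#'
#' A triangle mesh with an outward orientation, fixed in either the femoral
#' or the tibial component frame.
#'
#' @param vertices n x 3 numeric matrix, mm.
#' @param faces m x 3 integer matrix of 1-based vertex indices, wound so that
#'   face normals point out of the component material.
#' @param frame `"femoral"` or `"tibial"`.
#' @return An object of class `implant_surface`.
#' @export
implant_surface <- function(vertices, faces, frame = c("femoral", "tibial")) {
  frame <- match.arg(frame)
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3)
  stopifnot(ncol(vertices) == 3, nrow(faces) >= 1)
  if (max(faces) > nrow(vertices) || min(faces) < 1)
    stop("face indices out of range")
  if (any(face_areas(vertices, faces) < 1e-9))
    stop("mesh contains degenerate faces")
  structure(list(vertices = vertices, faces = faces, frame = frame),
            class = "implant_surface")
}

#' @export
print.implant_surface <- function(x, ...) {
  cat(sprintf("implant_surface (%s frame): %d vertices, %d faces\n",
              x$frame, nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

#' Per-face geometry of a triangle mesh
#'
#' @param vertices n x 3 vertex matrix (mm).
#' @param faces m x 3 index matrix.
#' @return `face_areas`: areas in mm^2; `face_centroids`: m x 3 centroids;
#'   `face_normals`: m x 3 unit normals (winding order).
#' @export
face_areas <- function(vertices, faces) {
  a <- vertices[faces[, 1], , drop = FALSE]
  e1 <- vertices[faces[, 2], , drop = FALSE] - a
  e2 <- vertices[faces[, 3], , drop = FALSE] - a
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  0.5 * sqrt(rowSums(cr^2))
}

#' @rdname face_areas
#' @export
face_centroids <- function(vertices, faces) {
  (vertices[faces[, 1], , drop = FALSE] +
     vertices[faces[, 2], , drop = FALSE] +
     vertices[faces[, 3], , drop = FALSE]) / 3
}

#' @rdname face_areas
#' @export
face_normals <- function(vertices, faces) {
  a <- vertices[faces[, 1], , drop = FALSE]
  e1 <- vertices[faces[, 2], , drop = FALSE] - a
  e2 <- vertices[faces[, 3], , drop = FALSE] - a
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  cr / sqrt(rowSums(cr^2))
}

#' Write / read an implant surface as ASCII STL
#'
#' @param surface An [implant_surface()].
#' @param path File path.
#' @param frame Component frame to assign on reading.
#' @return `write_surface_stl` returns `path` invisibly; `read_surface_stl`
#'   an [implant_surface()] (vertices are welded by exact coordinate match).
#' @export
write_surface_stl <- function(surface, path) {
  v <- surface$vertices
  f <- surface$faces
  n <- face_normals(v, f)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("solid %s", surface$frame), con)
  for (i in seq_len(nrow(f))) {
    writeLines(c(
      sprintf("  facet normal %.9g %.9g %.9g", n[i, 1], n[i, 2], n[i, 3]),
      "    outer loop",
      sprintf("      vertex %.9g %.9g %.9g",
              v[f[i, ], 1], v[f[i, ], 2], v[f[i, ], 3]),
      "    endloop",
      "  endfacet"), con)
  }
  writeLines(sprintf("endsolid %s", surface$frame), con)
  invisible(path)
}

#' @rdname write_surface_stl
#' @export
read_surface_stl <- function(path, frame = c("femoral", "tibial")) {
  frame <- match.arg(frame)
  lines <- readLines(path)
  vlines <- grep("^\\s*vertex\\s", lines, value = TRUE)
  coords <- do.call(rbind, lapply(strsplit(trimws(vlines), "\\s+"), function(x) {
    as.numeric(x[2:4])
  }))
  key <- apply(coords, 1, paste, collapse = ",")
  uniq <- !duplicated(key)
  verts <- coords[uniq, , drop = FALSE]
  idx <- match(key, key[uniq])
  faces <- matrix(idx, ncol = 3, byrow = TRUE)
  implant_surface(verts, faces, frame)
}

#' Write / read an implant surface as Wavefront OBJ
#'
#' @inheritParams write_surface_stl
#' @export
write_surface_obj <- function(surface, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("o %s", surface$frame), con)
  v <- surface$vertices
  writeLines(sprintf("v %.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]), con)
  f <- surface$faces
  writeLines(sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3]), con)
  invisible(path)
}

#' @rdname write_surface_obj
#' @export
read_surface_obj <- function(path, frame = c("femoral", "tibial")) {
  frame <- match.arg(frame)
  lines <- readLines(path)
  vl <- strsplit(grep("^v ", lines, value = TRUE), "\\s+")
  fl <- strsplit(grep("^f ", lines, value = TRUE), "\\s+")
  verts <- do.call(rbind, lapply(vl, function(x) as.numeric(x[2:4])))
  faces <- do.call(rbind, lapply(fl, function(x) {
    as.integer(sub("/.*", "", x[2:4]))
  }))
  implant_surface(verts, faces, frame)
}
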