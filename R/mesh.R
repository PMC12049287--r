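#' Triangle mesh
#'
#' Vertices in millimetres in the world frame, faces as 1-based vertex-index
#' triples.  Used for both extracted bone surfaces and implant tray (CAD)
#' geometry.
#'
#' @param vertices numeric n x 3 matrix of vertex coordinates, mm.
#' @param faces integer m x 3 matrix of vertex indices (1-based).
#' @return an object of class `triangle_mesh`.
#' @export
triangle_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) rf_stop("mesh", "vertices must be n x 3")
  if (nrow(vertices) < 1L) rf_stop("mesh", "mesh has no vertices")
  if (ncol(faces) != 3L) rf_stop("mesh", "faces must be m x 3")
  if (nrow(faces) < 1L) rf_stop("mesh", "mesh has no faces")
  if (any(!is.finite(vertices))) rf_stop("mesh", "non-finite vertex coordinates")
  if (min(faces) < 1L || max(faces) > nrow(vertices))
    rf_stop("mesh", "face indices out of range")
  degen <- faces[, 1] == faces[, 2] | faces[, 2] == faces[, 3] |
    faces[, 1] == faces[, 3]
  if (any(degen))
    rf_stop("mesh", "%d degenerate faces (repeated vertex index)", sum(degen))
  dimnames(vertices) <- NULL
  dimnames(faces) <- NULL
  structure(list(vertices = vertices, faces = faces), class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  m <- mesh_metrics(x)
  cat(sprintf("<triangle_mesh> %d vertices, %d faces, area %.2f mm^2%s\n",
              nrow(x$vertices), nrow(x$faces), m$area,
              if (is.na(m$volume)) " (open)" else
                sprintf(", volume %.2f mm^3", m$volume)))
  invisible(x)
}

# every edge shared by exactly two faces?
mesh_is_closed <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  all(table(key) == 2L)
}

#' Surface area and enclosed volume of a mesh
#'
#' Area is the sum of triangle areas.  The enclosed volume uses the
#' divergence theorem (sum of signed tetrahedron volumes against the
#' origin); it is only meaningful for closed meshes and is reported as `NA`
#' (with a warning) for open ones.  Consistently outward-oriented meshes
#' give a positive signed volume; the absolute value is returned.
#'
#' @param mesh a [triangle_mesh()].
#' @return list with elements `area` (mm^2), `volume` (mm^3 or `NA`), and
#'   `closed` (logical).
#' @export
mesh_metrics <- function(mesh) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  u <- b - a
  w <- c_ - a
  cr <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
              u[, 3] * w[, 1] - u[, 1] * w[, 3],
              u[, 1] * w[, 2] - u[, 2] * w[, 1])
  area <- sum(sqrt(rowSums(cr^2))) / 2
  closed <- mesh_is_closed(mesh)
  if (closed) {
    signed <- sum(a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) +
                  a[, 2] * (b[, 3] * c_[, 1] - b[, 1] * c_[, 3]) +
                  a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])) / 6
    volume <- abs(signed)
  } else {
    warning("open mesh: enclosed volume reported as NA")
    volume <- NA_real_
  }
  list(area = area, volume = volume, closed = closed)
}

# signed enclosed volume (positive for outward orientation); no closedness
# check -- internal, used by orientation tests
mesh_signed_volume <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) +
      a[, 2] * (b[, 3] * c_[, 1] - b[, 1] * c_[, 3]) +
      a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])) / 6
}

# merge vertices with exactly identical coordinates (STL facet soup -> mesh)
weld_vertices <- function(vertices, faces) {
  key <- sprintf("%.17g_%.17g_%.17g", vertices[, 1], vertices[, 2],
                 vertices[, 3])
  first <- !duplicated(key)
  map <- match(key, key[first]) # position in the deduplicated set = new id
  list(vertices = vertices[first, , drop = FALSE],
       faces = matrix(map[faces], ncol = 3))
}

# area-weighted centroid of the surface
mesh_centroid <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  u <- b - a
  w <- c_ - a
  cr <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
              u[, 3] * w[, 1] - u[, 1] * w[, 3],
              u[, 1] * w[, 2] - u[, 2] * w[, 1])
  ta <- sqrt(rowSums(cr^2)) / 2
  ctr <- (a + b + c_) / 3
  colSums(ctr * ta) / sum(ta)
}
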