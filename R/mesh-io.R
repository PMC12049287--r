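#' Read a triangle mesh
#'
#' Supported formats: STL (binary or ASCII), PLY (ASCII), OBJ.  STL stores a
#' facet soup (three vertices per facet); vertices are merged by exact
#' coordinate match on read so shared vertices become shared indices.  Face
#' orientation is preserved as stored.  STL carries no unit field; it is
#' assumed to be millimetres (apply `scale` otherwise).
#'
#' @param path mesh file path.
#' @param scale optional multiplicative factor applied to all coordinates.
#' @return a [triangle_mesh()].
#' @export
read_mesh <- function(path, scale = 1) {
  if (!file.exists(path)) rf_stop("volio", "no such file: %s", path)
  lp <- tolower(path)
  mesh <- if (grepl("\\.stl$", lp)) read_stl(path)
  else if (grepl("\\.ply$", lp)) read_ply(path)
  else if (grepl("\\.obj$", lp)) read_obj(path)
  else rf_stop("volio", "unrecognized mesh format: %s", basename(path))
  if (scale != 1) mesh$vertices <- mesh$vertices * scale
  mesh
}

#' Write a triangle mesh
#'
#' STL (binary) or PLY (ASCII).  Output is byte-stable: writing the same
#' mesh twice yields identical files.
#'
#' @param mesh a [triangle_mesh()].
#' @param path output path ending in `.stl` or `.ply`.
#' @param ascii write ASCII STL instead of binary.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, ascii = FALSE) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  lp <- tolower(path)
  ok <- tryCatch({
    if (grepl("\\.stl$", lp)) {
      if (ascii) write_stl_ascii(mesh, path) else write_stl_binary(mesh, path)
    } else if (grepl("\\.ply$", lp)) write_ply(mesh, path)
    else rf_stop("volio", "unsupported mesh output format: %s", basename(path))
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) rf_stop("volio", "cannot write %s: %s", path, conditionMessage(ok))
  invisible(path)
}

## ---- STL -------------------------------------------------------------------

read_stl <- function(path) {
  sz <- file.size(path)
  if (sz < 15) rf_stop("volio", "truncated STL: %s", basename(path))
  head_raw <- readBin(path, "raw", min(sz, 512))
  is_ascii <- identical(rawToChar(head_raw[1:5]), "solid") &&
    # binary files may also start with "solid": check facet keyword in text
    grepl("facet", rawToChar(head_raw[head_raw != as.raw(0)]), fixed = TRUE)
  if (is_ascii) read_stl_ascii(path) else read_stl_binary(path)
}

read_stl_binary <- function(path) {
  sz <- file.size(path)
  if (sz < 84) rf_stop("volio", "truncated binary STL: %s", basename(path))
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", 80)
  ntri <- readBin(con, "integer", 1, size = 4, endian = "little")
  if (ntri <= 0 || sz < 84 + ntri * 50)
    rf_stop("volio", "corrupt binary STL (declares %d facets, %d bytes): %s",
            ntri, sz, basename(path))
  rec <- readBin(con, "raw", ntri * 50)
  rec <- matrix(rec, nrow = 50)
  floats <- readBin(as.vector(rec[1:48, ]), "double", n = ntri * 12, size = 4,
                    endian = "little")
  fm <- matrix(floats, nrow = 12) # per facet: normal, v1, v2, v3
  verts <- rbind(t(fm[4:6, , drop = FALSE]),
                 t(fm[7:9, , drop = FALSE]),
                 t(fm[10:12, , drop = FALSE]))
  # interleave back to per-facet order v1,v2,v3
  idx <- as.vector(t(matrix(seq_len(3 * ntri), ncol = 3)))
  verts <- verts[idx, , drop = FALSE]
  faces <- matrix(seq_len(3 * ntri), ncol = 3, byrow = TRUE)
  w <- weld_vertices(verts, faces)
  triangle_mesh(w$vertices, w$faces)
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (length(vl) == 0 || length(vl) %% 3 != 0)
    rf_stop("volio", "corrupt ASCII STL (vertex count %d): %s",
            length(vl), basename(path))
  nums <- t(vapply(strsplit(trimws(vl), "\\s+"),
                   function(x) as.numeric(x[2:4]), numeric(3)))
  faces <- matrix(seq_len(nrow(nums)), ncol = 3, byrow = TRUE)
  w <- weld_vertices(nums, faces)
  triangle_mesh(w$vertices, w$faces)
}

write_stl_binary <- function(mesh, path) {
  v <- mesh$vertices
  f <- mesh$faces
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- charToRaw(sprintf("%-80s", "resectfit binary STL"))[1:80]
  writeBin(hdr, con)
  writeBin(nrow(f), con, size = 4, endian = "little")
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  u <- b - a; w <- c_ - a
  n <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
             u[, 3] * w[, 1] - u[, 1] * w[, 3],
             u[, 1] * w[, 2] - u[, 2] * w[, 1])
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n <- n / len
  block <- t(cbind(n, a, b, c_)) # 12 floats per facet, column = facet
  fl <- writeBin(as.vector(block), raw(), size = 4, endian = "little")
  fl <- matrix(fl, nrow = 48)
  rec <- rbind(fl, matrix(as.raw(0), 2, ncol(fl)))
  writeBin(as.vector(rec), con)
  invisible(path)
}

write_stl_ascii <- function(mesh, path) {
  v <- mesh$vertices
  f <- mesh$faces
  con <- file(path, "w")
  on.exit(close(con))
  cat("solid resectfit\n", file = con)
  for (i in seq_len(nrow(f))) {
    tri <- v[f[i, ], , drop = FALSE]
    u <- tri[2, ] - tri[1, ]; w <- tri[3, ] - tri[1, ]
    n <- c(u[2] * w[3] - u[3] * w[2], u[3] * w[1] - u[1] * w[3],
           u[1] * w[2] - u[2] * w[1])
    l <- sqrt(sum(n^2)); if (l > 0) n <- n / l
    cat(sprintf("facet normal %.9g %.9g %.9g\n outer loop\n", n[1], n[2], n[3]),
        file = con)
    for (q in 1:3)
      cat(sprintf("  vertex %.9g %.9g %.9g\n", tri[q, 1], tri[q, 2], tri[q, 3]),
          file = con)
    cat(" endloop\nendfacet\n", file = con)
  }
  cat("endsolid resectfit\n", file = con)
  invisible(path)
}

## ---- PLY (ASCII) -----------------------------------------------------------

read_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3 || trimws(lines[1]) != "ply")
    rf_stop("volio", "corrupt PLY header: %s", basename(path))
  endh <- match("end_header", trimws(lines))
  if (is.na(endh)) rf_stop("volio", "corrupt PLY (no end_header): %s", basename(path))
  hdr <- trimws(lines[seq_len(endh)])
  if (!any(grepl("^format ascii", hdr)))
    rf_stop("volio", "only ASCII PLY supported: %s", basename(path))
  ev <- regmatches(hdr, regexec("^element vertex (\\d+)", hdr))
  nv <- as.integer(unlist(lapply(ev, `[`, 2)))
  nv <- nv[!is.na(nv)]
  ef <- regmatches(hdr, regexec("^element face (\\d+)", hdr))
  nf <- as.integer(unlist(lapply(ef, `[`, 2)))
  nf <- nf[!is.na(nf)]
  if (length(nv) != 1 || length(nf) != 1)
    rf_stop("volio", "PLY must declare vertex and face elements: %s", basename(path))
  body <- lines[(endh + 1):length(lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < nv + nf) rf_stop("volio", "truncated PLY body: %s", basename(path))
  vt <- t(vapply(strsplit(trimws(body[seq_len(nv)]), "\\s+"),
                 function(x) as.numeric(x[1:3]), numeric(3)))
  fl <- strsplit(trimws(body[nv + seq_len(nf)]), "\\s+")
  faces <- do.call(rbind, lapply(fl, function(x) {
    cnt <- as.integer(x[1])
    if (cnt != 3) rf_stop("volio", "non-triangular PLY face")
    as.integer(x[2:4]) + 1L
  }))
  triangle_mesh(vt, faces)
}

write_ply <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  v <- mesh$vertices
  f <- mesh$faces
  writeLines(c(
    "ply", "format ascii 1.0", "comment resectfit",
    sprintf("element vertex %d", nrow(v)),
    "property double x", "property double y", "property double z",
    sprintf("element face %d", nrow(f)),
    "property list uchar int vertex_indices",
    "end_header"
  ), con)
  writeLines(sprintf("%.17g %.17g %.17g", v[, 1], v[, 2], v[, 3]), con)
  writeLines(sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L), con)
  invisible(path)
}

## ---- OBJ (read-only) -------------------------------------------------------

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^v\\s", lines, value = TRUE)
  fl <- grep("^f\\s", lines, value = TRUE)
  if (length(vl) == 0 || length(fl) == 0)
    rf_stop("volio", "corrupt OBJ (no vertices or faces): %s", basename(path))
  vt <- t(vapply(strsplit(trimws(vl), "\\s+"),
                 function(x) as.numeric(x[2:4]), numeric(3)))
  faces <- do.call(rbind, lapply(strsplit(trimws(fl), "\\s+"), function(x) {
    ids <- as.integer(sub("/.*", "", x[-1]))
    if (length(ids) != 3) rf_stop("volio", "non-triangular OBJ face")
    ids
  }))
  triangle_mesh(vt, faces)
}

#' Export per-vertex distances alongside a mesh
#'
#' Writes an ASCII PLY with a `quality` scalar per vertex, plus a CSV of
#' vertex coordinates and distances.
#'
#' @param mesh the bone [triangle_mesh()].
#' @param dm the matching [signed_distance()] map.
#' @param ply_path,csv_path output paths (either may be `NULL` to skip).
#' @return invisibly, the paths written.
#' @export
export_distances <- function(mesh, dm, ply_path = NULL, csv_path = NULL) {
  stopifnot(inherits(dm, "distance_map"))
  if (nrow(mesh$vertices) != length(dm$values))
    rf_stop("distmap", "mesh and distance map sizes differ")
  if (!is.null(ply_path)) {
    con <- file(ply_path, "w")
    v <- mesh$vertices
    f <- mesh$faces
    writeLines(c(
      "ply", "format ascii 1.0", "comment resectfit distance export",
      sprintf("element vertex %d", nrow(v)),
      "property double x", "property double y", "property double z",
      "property double quality",
      sprintf("element face %d", nrow(f)),
      "property list uchar int vertex_indices",
      "end_header"
    ), con)
    writeLines(sprintf("%.17g %.17g %.17g %.17g", v[, 1], v[, 2], v[, 3],
                       dm$values), con)
    writeLines(sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L), con)
    close(con)
  }
  if (!is.null(csv_path)) {
    df <- data.frame(x = mesh$vertices[, 1], y = mesh$vertices[, 2],
                     z = mesh$vertices[, 3], distance = dm$values)
    write.csv(df, csv_path, row.names = FALSE)
  }
  invisible(c(ply_path, csv_path))
}
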