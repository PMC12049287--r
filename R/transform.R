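#' Rigid (proper) transform
#'
#' A rotation plus translation mapping bone coordinates into the implant
#' frame: `x -> R x + t`.
#'
#' @param rotation 3 x 3 proper rotation matrix (orthonormal, det +1).
#' @param translation numeric length-3, mm.
#' @return an object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  if (!all(dim(rotation) == c(3L, 3L)))
    rf_stop("transform", "rotation must be 3 x 3")
  if (length(translation) != 3L)
    rf_stop("transform", "translation must have length 3")
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9)
    rf_stop("transform", "rotation is not orthonormal within 1e-9")
  if (abs(det(rotation) - 1) > 1e-9)
    rf_stop("transform", "rotation determinant is not +1 within 1e-9")
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform> angle %.3f deg, translation %.3f mm\n",
              rotation_angle_deg(x$rotation),
              sqrt(sum(x$translation^2))))
  invisible(x)
}

# rotation angle in degrees from a rotation matrix
rotation_angle_deg <- function(R) {
  ct <- (sum(diag(R)) - 1) / 2
  acos(max(-1, min(1, ct))) * 180 / pi
}

#' Apply a rigid transform to a mesh
#'
#' Vertices map as `R v + t`; faces are unchanged.
#'
#' @param mesh a [triangle_mesh()].
#' @param transform a [rigid_transform()].
#' @return the transformed [triangle_mesh()].
#' @export
apply_transform <- function(mesh, transform) {
  stopifnot(inherits(mesh, "triangle_mesh"), inherits(transform, "rigid_transform"))
  v <- mesh$vertices %*% t(transform$rotation)
  v <- sweep(v, 2, transform$translation, "+")
  triangle_mesh(v, mesh$faces)
}

#' Invert a rigid transform
#' @param transform a [rigid_transform()].
#' @return the inverse [rigid_transform()].
#' @export
invert_transform <- function(transform) {
  Rt <- t(transform$rotation)
  rigid_transform(Rt, -as.vector(Rt %*% transform$translation))
}

#' Compose rigid transforms
#'
#' `compose_transform(t1, t2)` applies `t2` first, then `t1`
#' (`x -> t1(t2(x))`).
#'
#' @param t1,t2 [rigid_transform()] objects.
#' @return the composed [rigid_transform()].
#' @export
compose_transform <- function(t1, t2) {
  rigid_transform(t1$rotation %*% t2$rotation,
                  as.vector(t1$rotation %*% t2$translation) + t1$translation)
}

#' Serialize a rigid transform as a 4 x 4 homogeneous matrix
#'
#' Plain-text sidecar format: four rows of four numbers.
#'
#' @param transform a [rigid_transform()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_transform <- function(transform, path) {
  m <- rbind(cbind(transform$rotation, transform$translation), c(0, 0, 0, 1))
  lines <- apply(m, 1, function(r) paste(sprintf("%.17g", r), collapse = " "))
  writeLines(lines, path)
  invisible(path)
}

#' Read a rigid transform from a 4 x 4 homogeneous matrix file
#' @param path file written by [write_transform()].
#' @return a [rigid_transform()].
#' @export
read_transform <- function(path) {
  if (!file.exists(path)) rf_stop("transform", "no such file: %s", path)
  m <- unname(as.matrix(read.table(path)))
  if (!all(dim(m) == c(4, 4))) rf_stop("transform", "expected a 4 x 4 matrix")
  rigid_transform(m[1:3, 1:3], m[1:3, 4])
}

# small helpers used across modules
rotation_about_axis <- function(axis, angle_deg) {
  a <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}
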