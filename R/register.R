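# closest points from a point set to a mesh surface (point-to-triangle)
closest_to_mesh <- function(points, mesh, signed = FALSE) {
  res <- cpp_closest_signed(points, mesh$vertices, mesh$faces, signed)
  res
}

# deterministic subsample of vertex rows (evenly spaced; no RNG)
subsample_rows <- function(n, max_points) {
  if (n <= max_points) return(seq_len(n))
  unique(round(seq(1, n, length.out = max_points)))
}

#' Coarse initial alignment by centroid and principal axes
#'
#' Translates the moving mesh so its area-weighted surface centroid matches
#' the fixed mesh's, and rotates its principal vertex-covariance axes onto
#' the fixed mesh's.  Principal axes leave four proper-rotation sign
#' choices; the candidate with the lowest RMS closest-point distance to the
#' fixed surface is returned.  For nearly spherical meshes the axes are
#' arbitrary but the centroid match still holds.
#'
#' @param moving,fixed [triangle_mesh()] objects with at least 4
#'   non-coplanar vertices.
#' @param max_points vertex subsample cap used for candidate scoring.
#' @return a [rigid_transform()] mapping `moving` into the `fixed` frame.
#' @export
initial_align <- function(moving, fixed, max_points = 1000L) {
  stopifnot(inherits(moving, "triangle_mesh"), inherits(fixed, "triangle_mesh"))
  axes_of <- function(mesh) {
    v <- mesh$vertices
    cv <- stats::cov(v)
    eg <- eigen(cv, symmetric = TRUE)
    if (eg$values[3] < 1e-12 * max(eg$values[1], 1))
      rf_stop("register", "degenerate (coplanar) mesh: principal axes undefined")
    E <- eg$vectors
    if (det(E) < 0) E[, 3] <- -E[, 3]
    E
  }
  Em <- axes_of(moving)
  Ef <- axes_of(fixed)
  cm <- mesh_centroid(moving)
  cf <- mesh_centroid(fixed)
  flips <- list(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  sub <- subsample_rows(nrow(moving$vertices), max_points)
  pts <- moving$vertices[sub, , drop = FALSE]
  cand <- lapply(flips, function(s) {
    R <- Ef %*% diag(s) %*% t(Em)
    t_ <- cf - as.vector(R %*% cm)
    moved <- sweep(pts %*% t(R), 2, t_, "+")
    d <- closest_to_mesh(moved, fixed)$distance
    list(tr = rigid_transform(R, t_), rms = sqrt(mean(d^2)),
         angle = rotation_angle_deg(R))
  })
  rms <- vapply(cand, `[[`, 0, "rms")
  # both meshes arrive in anatomically labelled frames, so candidates whose
  # RMS nearly ties (a symmetric tray cannot distinguish them) are resolved
  # toward the smallest rotation rather than an arbitrary axis flip
  near <- which(rms <= min(rms) * 1.02 + 1e-12)
  pick <- near[which.min(vapply(cand[near], `[[`, 0, "angle"))]
  cand[[pick]]$tr
}

#' Trimmed iterative-closest-point rigid registration
#'
#' Refines an initial pose by alternating (a) closest-point correspondence
#' from moving vertices to the nearest point on the fixed mesh's triangles
#' (point-to-triangle, since bone meshes are far denser than tray CAD
#' meshes) and (b) a least-squares rigid update (Kabsch/SVD).  Each
#' iteration the `trim_fraction` worst correspondences are discarded: the
#' bone specimen legitimately overhangs the implant -- that overhang is the
#' measurand -- so untrimmed least squares would tilt the pose to bury it.
#' Iterations stop when the trimmed RMS improves by less than `tol` (mm) or
#' at the iteration cap.  The trimmed RMS never increases between accepted
#' iterations.
#'
#' @param moving,fixed [triangle_mesh()] objects (bone is moving, implant
#'   fixed; downstream reporting is in the implant frame).
#' @param init initial [rigid_transform()]; default [initial_align()].
#' @param max_iterations iteration cap (>= 1).
#' @param tol minimum RMS improvement (mm) to continue.
#' @param trim_fraction fraction of worst correspondences discarded.
#' @param max_points deterministic cap on moving vertices used per
#'   iteration.
#' @return a `registration_result`: list with `transform`
#'   ([rigid_transform()]), `rms` (mm, trimmed), `iterations`, `converged`,
#'   and `rms_history`.
#' @export
icp <- function(moving, fixed, init = NULL, max_iterations = 50L,
                tol = 1e-6, trim_fraction = 0.1, max_points = 2000L) {
  stopifnot(inherits(moving, "triangle_mesh"), inherits(fixed, "triangle_mesh"))
  if (any(!is.finite(moving$vertices)) || any(!is.finite(fixed$vertices)))
    rf_stop("register", "non-finite vertices")
  if (max_iterations < 1L) rf_stop("register", "max_iterations must be >= 1")
  if (is.null(init)) init <- initial_align(moving, fixed)
  sub <- subsample_rows(nrow(moving$vertices), max_points)
  pts0 <- moving$vertices[sub, , drop = FALSE]
  keep_n <- max(3L, floor(nrow(pts0) * (1 - trim_fraction)))
  cur <- init
  prev <- init
  rms_hist <- numeric(0)
  prev_rms <- Inf
  converged <- FALSE
  iters <- 0L
  for (it in seq_len(max_iterations)) {
    iters <- it
    pts <- sweep(pts0 %*% t(cur$rotation), 2, cur$translation, "+")
    cp <- closest_to_mesh(pts, fixed)
    d <- abs(cp$distance)
    keep <- order(d)[seq_len(keep_n)]
    rms <- sqrt(mean(d[keep]^2))
    if (prev_rms - rms < tol && it > 1L) {
      converged <- TRUE
      if (rms > prev_rms) {
        # the last update degraded the fit: keep the previous pose so the
        # accepted-iteration RMS sequence stays non-increasing
        cur <- prev
        iters <- it - 1L
      } else rms_hist <- c(rms_hist, rms)
      break
    }
    rms_hist <- c(rms_hist, rms)
    prev_rms <- rms
    prev <- cur
    # Kabsch on trimmed correspondences (source in ORIGINAL moving frame so
    # the update replaces, not compounds, the transform)
    src <- pts0[keep, , drop = FALSE]
    dst <- cp$closest[keep, , drop = FALSE]
    mu_s <- colMeans(src)
    mu_d <- colMeans(dst)
    H <- crossprod(sweep(src, 2, mu_s), sweep(dst, 2, mu_d))
    sv <- svd(H)
    S <- diag(c(1, 1, sign(det(sv$v %*% t(sv$u)))))
    R <- sv$v %*% S %*% t(sv$u)
    t_ <- mu_d - as.vector(R %*% mu_s)
    cur <- rigid_transform(R, t_)
  }
  structure(list(transform = cur, rms = rms_hist[length(rms_hist)],
                 iterations = iters, converged = converged,
                 rms_history = rms_hist),
            class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf("<registration_result> rms %.4g mm after %d iterations (%s)\n",
              x$rms, x$iterations,
              if (x$converged) "converged" else "iteration cap"))
  invisible(x)
}
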