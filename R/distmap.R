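#' Signed bone-to-implant surface distances
#'
#' For every bone-mesh vertex, the distance to the nearest point on any
#' implant triangle.  The sign is positive where the vertex lies on the
#' outward-normal side of the implant surface at that nearest point -- bone
#' standing proud of ("above") the component -- and negative otherwise.
#' Normals at closest points falling on implant edges or vertices use
#' angle-weighted pseudonormals, which give a correct inside/outside
#' classification there.  The mapping is asymmetric by design: the method
#' measures bone surplus over the component, not vice versa.
#'
#' Distances are stored in mm and reported in the requested unit; voxel
#' units divide mm by `voxel_size`.
#'
#' @param bone bone [triangle_mesh()], already in the implant frame.
#' @param implant implant tray [triangle_mesh()].
#' @param unit `"voxel"` (default) or `"mm"`.
#' @param voxel_size reference voxel edge length in mm (required for voxel
#'   units).
#' @return an object of class `distance_map`: per-vertex `values` in
#'   `unit`, plus `mm` (always), `unit`, and `voxel_size`.
#' @export
signed_distance <- function(bone, implant, unit = c("voxel", "mm"),
                            voxel_size = 1) {
  stopifnot(inherits(bone, "triangle_mesh"), inherits(implant, "triangle_mesh"))
  unit <- match.arg(unit)
  if (voxel_size <= 0) rf_stop("distmap", "voxel_size must be positive")
  res <- cpp_closest_signed(bone$vertices, implant$vertices, implant$faces, TRUE)
  mm <- res$distance
  values <- if (unit == "voxel") mm / voxel_size else mm
  structure(list(values = values, mm = mm, unit = unit,
                 voxel_size = voxel_size, n_vertices = nrow(bone$vertices)),
            class = "distance_map")
}

#' @export
print.distance_map <- function(x, ...) {
  cat(sprintf("<distance_map> %d vertices, unit %s: mean |d| %.3f, max %.3f\n",
              x$n_vertices, x$unit, mean(abs(x$values)), max(x$values)))
  invisible(x)
}

# unit conversion
distance_in <- function(dm, unit) {
  if (dm$unit == unit) return(dm$values)
  if (unit == "mm") return(dm$mm)
  dm$mm / dm$voxel_size
}

#' Summary statistics of a distance map
#'
#' Mean and standard deviation are taken over absolute distances (the
#' conventional "surface distance"); the maximum is over signed distances,
#' i.e. the highest elevation of bone above the implant.  The sample
#' (n - 1) standard-deviation convention is used.  The mean signed distance
#' is reported alongside.
#'
#' @param dm a [signed_distance()] map.
#' @return list with `mean_abs`, `sd_abs`, `max_signed`, `mean_signed`,
#'   `unit`.
#' @export
summarize_distances <- function(dm) {
  stopifnot(inherits(dm, "distance_map"))
  if (length(dm$values) == 0) rf_stop("distmap", "empty distance map")
  v <- dm$values
  list(mean_abs = mean(abs(v)),
       sd_abs = if (length(v) > 1) sd(abs(v)) else 0,
       max_signed = max(v),
       mean_signed = mean(v),
       unit = dm$unit)
}

.bin_labels <- c("Light Blue", "Dark Blue", "Red", "Green", "Yellow",
                 "Turquoise", "Orange", "Pink")
.bin_rgb <- rbind(
  c(0.53, 0.81, 0.98), # light blue
  c(0.00, 0.00, 0.55), # dark blue
  c(0.85, 0.10, 0.10), # red
  c(0.10, 0.60, 0.10), # green
  c(0.95, 0.90, 0.10), # yellow
  c(0.25, 0.88, 0.82), # turquoise
  c(1.00, 0.55, 0.00), # orange
  c(1.00, 0.45, 0.71)  # pink
)

#' Bin voxel-unit distances into the eight-band colour code
#'
#' Positive distances fall into half-open voxel bands `[0,1)` Light Blue,
#' `[1,2)` Dark Blue, `[2,3)` Red, `[3,4)` Green, `[4,5)` Yellow, `[5,6)`
#' Turquoise, `[6,7)` Orange, `[7,8)` Pink.  Values `>= 8` are counted as
#' overflow and values `< 0` (bone below the implant surface) as the
#' negative-side count.  Counts always sum to the vertex count.
#'
#' @param dm a [signed_distance()] map in voxel units (convert first
#'   otherwise).
#' @return an object of class `distance_binning`: `counts` (named, 8
#'   bands), `overflow`, `negative`, `total`.
#' @export
bin_distances <- function(dm) {
  stopifnot(inherits(dm, "distance_map"))
  if (dm$unit != "voxel")
    rf_stop("distmap", "binning is defined on voxel units; convert first")
  v <- dm$values
  counts <- vapply(seq_len(8), function(k) sum(v >= k - 1 & v < k), 0L)
  names(counts) <- .bin_labels
  out <- list(counts = counts, overflow = sum(v >= 8), negative = sum(v < 0),
              total = length(v))
  stopifnot(sum(counts) + out$overflow + out$negative == out$total)
  structure(out, class = "distance_binning")
}

#' @export
print.distance_binning <- function(x, ...) {
  cat("<distance_binning> (voxel units)\n")
  for (k in seq_len(8))
    cat(sprintf("  [%d,%d) %-10s %d\n", k - 1, k, names(x$counts)[k], x$counts[k]))
  cat(sprintf("  >= 8 (overflow)    %d\n  < 0  (below)       %d\n",
              x$overflow, x$negative))
  invisible(x)
}

# per-vertex RGB for a voxel-unit distance vector
distance_colors <- function(v) {
  col <- matrix(0.65, length(v), 3) # neutral grey for negative side
  pos <- v >= 0
  band <- pmin(floor(pmax(v, 0)) + 1, 8)
  col[pos, ] <- .bin_rgb[band[pos], , drop = FALSE]
  over <- v >= 8
  col[over, ] <- matrix(rep(c(0.3, 0.0, 0.3), each = sum(over)), ncol = 3)
  col
}

# camera rotations (world -> camera) for the six standardized views.
# World frame: +x medial (ML), +y anterior (AP), +z proximal (PD).
# Camera: x right, y up, z toward viewer.
standard_views <- function() {
  look <- function(dir, up) {
    dir <- dir / sqrt(sum(dir^2))
    up <- up - sum(up * dir) * dir
    up <- up / sqrt(sum(up^2))
    right <- c(up[2] * dir[3] - up[3] * dir[2],
               up[3] * dir[1] - up[1] * dir[3],
               up[1] * dir[2] - up[2] * dir[1])
    # rows: right, up, dir (dir points from scene toward the viewer)
    rbind(right, up, dir)
  }
  ob <- function(az_deg) {
    el <- 30 * pi / 180
    az <- az_deg * pi / 180
    # azimuth measured from anterior (+y), elevation above the axial plane
    c(sin(az) * cos(el), cos(az) * cos(el), sin(el))
  }
  list(
    anterior = look(c(0, 1, 0), c(0, 0, 1)),
    posterior = look(c(0, -1, 0), c(0, 0, 1)),
    lateral = look(c(-1, 0, 0), c(0, 0, 1)),   # viewed from the lateral side
    oblique_left = look(ob(-45), c(0, 0, 1)),
    oblique_right = look(ob(45), c(0, 0, 1)),
    proximal = look(c(0, 0, 1), c(0, 1, 0))
  )
}

#' Render the six standardized overlay views
#'
#' Orthographic renders from strictly anterior, posterior and lateral
#' directions, two 45-degree obliques (azimuth +/-45 degrees from anterior
#' at 30 degrees elevation) and one proximal (top) view.  The bone surface
#' is coloured by the eight-band distance code, the implant in neutral
#' grey.  Rendering is a deterministic software z-buffer: fixed inputs give
#' byte-identical PNG files.
#'
#' @param bone bone [triangle_mesh()] in the implant frame.
#' @param implant implant [triangle_mesh()].
#' @param dm [signed_distance()] map for `bone` (voxel units).
#' @param out_dir output directory (created if missing).
#' @param width,height image size in pixels.
#' @return character vector of the six file paths written.
#' @export
render_views <- function(bone, implant, dm, out_dir, width = 400L,
                         height = 400L) {
  stopifnot(inherits(dm, "distance_map"))
  if (length(dm$values) == 0 || length(dm$values) != nrow(bone$vertices))
    rf_stop("distmap", "distance map does not match the bone mesh")
  ok <- dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) rf_stop("distmap", "cannot create %s", out_dir)
  vb <- distance_in(dm, "voxel")
  nb <- nrow(bone$vertices)
  V <- rbind(bone$vertices, implant$vertices)
  F <- rbind(bone$faces, implant$faces + nb)
  C <- rbind(distance_colors(vb),
             matrix(0.75, nrow(implant$vertices), 3))
  views <- standard_views()
  paths <- character(0)
  for (nm in names(views)) {
    cam <- views[[nm]]
    Vc <- V %*% t(cam)
    # pad the window by 5% so silhouettes do not touch the border
    rx <- range(Vc[, 1]); ry <- range(Vc[, 2])
    cx <- mean(rx); cy <- mean(ry)
    half <- max(diff(rx), diff(ry)) / 2 * 1.05
    win <- c(cx - half, cx + half, cy - half, cy + half)
    img <- cpp_render_zbuffer(Vc, F, C, as.integer(width), as.integer(height),
                              win, c(1, 1, 1), 0.35)
    p <- file.path(out_dir, paste0("view_", nm, ".png"))
    png::writePNG(img, p)
    paths <- c(paths, p)
  }
  paths
}
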