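# run code under a deterministic, isolated RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Phantom specification
#'
#' Parameters of a synthetic resection specimen and its matching stand-in
#' implant tray.  The phantom is a rounded-rectangular prism, not an
#' anatomic plateau: the quantities under study (wedge surplus, quotient,
#' sclerosis fraction) are geometry-level, so a shape with closed-form
#' ground truth is preferable to unverifiable anatomic realism.
#'
#' The specimen base and the tray share footprint and thickness, so a
#' zero-degree wedge phantom matches the tray exactly (zero surplus).  A
#' positive `wedge_angle_deg` adds a wedge whose height rises linearly from
#' 0 at the central edge to `ml_width * tan(angle)` at the medial edge --
#' the shape a perpendicular saw cut produces on a varus joint line.
#'
#' @param wedge_angle_deg coronal wedge angle in degrees; 0 = rectangular
#'   specimen.  Must be < 45.
#' @param ml_width,ap_depth,thickness_mm footprint and base thickness, mm.
#' @param corner_radius_mm footprint corner rounding, mm.
#' @param spacing_mm isotropic voxel size, mm.
#' @param grey_background,grey_spongious,grey_cortical,grey_sclerotic grey
#'   levels (must be ordered background < spongious < sclerotic).
#' @param noise_sd acquisition noise, grey units.
#' @param sclerotic_fraction fraction of the distal face that is sclerotic,
#'   in `[0, 1)`.
#' @param tilt_deg rigid tilt of the specimen about the AP axis, degrees.
#' @param container include a container wall at the volume border (crop
#'   testing).
#' @param margin_voxels background margin around the specimen.
#' @param seed integer seed driving all phantom randomness.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(wedge_angle_deg = 0,
                         ml_width = 25, ap_depth = 40, thickness_mm = 4,
                         corner_radius_mm = 2,
                         spacing_mm = 0.5,
                         grey_background = 0, grey_spongious = 120,
                         grey_cortical = 200, grey_sclerotic = 280,
                         noise_sd = 15,
                         sclerotic_fraction = 0.1,
                         tilt_deg = 0,
                         container = FALSE,
                         margin_voxels = 4L,
                         seed = 1L) {
  if (wedge_angle_deg < 0 || wedge_angle_deg >= 45)
    rf_stop("synth", "wedge angle must lie in [0, 45) degrees")
  if (ml_width <= 0 || ap_depth <= 0 || thickness_mm <= 0 || spacing_mm <= 0)
    rf_stop("synth", "dimensions and spacing must be positive")
  if (corner_radius_mm < 0 || corner_radius_mm > min(ml_width, ap_depth) / 2)
    rf_stop("synth", "corner radius out of range")
  if (sclerotic_fraction < 0 || sclerotic_fraction >= 1)
    rf_stop("synth", "sclerotic fraction must lie in [0, 1)")
  if (!(grey_background < grey_spongious && grey_spongious < grey_sclerotic))
    rf_stop("synth", "grey levels must be ordered background < spongious < sclerotic")
  structure(list(
    wedge_angle_deg = wedge_angle_deg, ml_width = ml_width,
    ap_depth = ap_depth, thickness_mm = thickness_mm,
    corner_radius_mm = corner_radius_mm, spacing_mm = spacing_mm,
    grey_background = grey_background, grey_spongious = grey_spongious,
    grey_cortical = grey_cortical, grey_sclerotic = grey_sclerotic,
    noise_sd = noise_sd, sclerotic_fraction = sclerotic_fraction,
    tilt_deg = tilt_deg, container = isTRUE(container),
    margin_voxels = as.integer(margin_voxels), seed = as.integer(seed)
  ), class = "phantom_spec")
}

# rounded-rectangle area (closed form)
rounded_rect_area <- function(w, d, r) w * d - (4 - pi) * r^2

# is (x, y) inside the rounded rectangle [0,w] x [0,d] with corner radius r?
in_rounded_rect <- function(x, y, w, d, r) {
  cx <- pmin(pmax(x, r), w - r)
  cy <- pmin(pmax(y, r), d - r)
  (x - cx)^2 + (y - cy)^2 <= r^2
}

# counter-clockwise outline of the footprint (z = 0 plane), closed-form area
footprint_outline <- function(w, d, r, seg_per_corner = 12L) {
  if (r == 0) return(cbind(c(0, w, w, 0), c(0, 0, d, d)))
  th <- function(from) from + seq(0, pi / 2, length.out = seg_per_corner + 1L)
  arc <- function(cx, cy, from) cbind(cx + r * cos(th(from)), cy + r * sin(th(from)))
  rbind(
    arc(w - r, r, -pi / 2),   # bottom-right corner
    arc(w - r, d - r, 0),     # top-right
    arc(r, d - r, pi / 2),    # top-left
    arc(r, r, pi)             # bottom-left
  )
}

#' Generate a stand-in implant tray mesh
#'
#' A closed, outward-oriented rounded-rectangular tray of uniform
#' thickness: footprint `ml_width x ap_depth` with rounded corners,
#' spanning `z` in `[0, thickness_mm]` in the implant frame (`+x` medial,
#' `+y` anterior, `+z` proximal).  Deterministic: the same spec always
#' yields the bit-identical mesh.
#'
#' @param spec a [phantom_spec()].
#' @return a closed [triangle_mesh()].
#' @export
make_implant_mesh <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  P <- footprint_outline(spec$ml_width, spec$ap_depth, spec$corner_radius_mm)
  # drop duplicated arc junction points
  P <- P[!duplicated(round(P, 12)), , drop = FALSE]
  n <- nrow(P)
  h <- spec$thickness_mm
  ctr <- c(mean(P[, 1]), mean(P[, 2]))
  # vertices: bottom ring, top ring, bottom centre, top centre
  V <- rbind(cbind(P, 0), cbind(P, h), c(ctr, 0), c(ctr, h))
  cb <- 2L * n + 1L
  ct <- 2L * n + 2L
  nxt <- c(seq_len(n)[-1], 1L)
  F <- rbind(
    cbind(cb, nxt, seq_len(n)),               # bottom cap (normal -z)
    cbind(ct, n + seq_len(n), n + nxt),       # top cap (normal +z)
    cbind(seq_len(n), nxt, n + nxt),          # side, lower triangles
    cbind(seq_len(n), n + nxt, n + seq_len(n)) # side, upper triangles
  )
  mesh <- triangle_mesh(V, F)
  if (mesh_signed_volume(mesh) < 0)
    mesh <- triangle_mesh(V, F[, c(1, 3, 2)])
  mesh
}

#' Generate a resection-specimen phantom volume with ground truth
#'
#' Voxelises the specimen prism (base plus optional wedge) on an isotropic
#' grid with a background margin, assigns grey levels (spongious bulk,
#' sclerotic patch on the distal face), adds seeded Gaussian noise, and
#' optionally tilts the specimen or adds a container wall at the volume
#' border.  Every ground-truth field is recomputable in closed form from
#' the phantom spec.
#'
#' @param spec a [phantom_spec()].
#' @return list with `volume` (a [volume_image()]) and `truth`: bone voxel
#'   count, analytic prism volume (mm^3), expected per-compartment max
#'   elevations (mm and voxel), exact sclerotic fraction of the distal
#'   face, applied tilt transform, distal-face slice index, and a crop box
#'   excluding the container.
#' @export
make_resection_volume <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  sp <- spec$spacing_mm
  m <- spec$margin_voxels
  w <- spec$ml_width
  dpt <- spec$ap_depth
  th <- spec$thickness_mm
  alpha <- spec$wedge_angle_deg * pi / 180
  hmax <- th + w * tan(alpha)
  # grid: bone occupies x in [0,w], y in [0,d], z in [0, hmax] before tilt;
  # tilt enlarges the needed z range by at most w*sin(|tilt|)
  tilt <- spec$tilt_deg * pi / 180
  zpad <- abs(sin(tilt)) * max(w, dpt)
  nx <- ceiling(w / sp) + 2 * m
  ny <- ceiling(dpt / sp) + 2 * m
  nz <- ceiling((hmax + zpad) / sp) + 2 * m + ceiling(zpad / sp)
  # voxel centres sit at half-integer multiples of the spacing so no centre
  # lies exactly on a specimen face (unbiased voxelisation)
  origin <- c((-m + 0.5) * sp, (-m + 0.5) * sp,
              (-(m + ceiling(zpad / sp)) + 0.5) * sp)
  ii <- seq_len(nx); jj <- seq_len(ny); kk <- seq_len(nz)
  xs <- origin[1] + (ii - 1) * sp
  ys <- origin[2] + (jj - 1) * sp
  zs <- origin[3] + (kk - 1) * sp
  g <- expand.grid(x = xs, y = ys, z = zs)
  pts <- as.matrix(g)
  # tilt about the AP axis through the specimen centre (inverse-map voxels)
  Rt <- rotation_about_axis(c(0, 1, 0), spec$tilt_deg)
  ctr <- c(w / 2, dpt / 2, th / 2)
  if (spec$tilt_deg != 0) {
    pts <- sweep(sweep(pts, 2, ctr) %*% Rt, 2, ctr, "+") # R^T via row-multiply
  }
  inside2d <- in_rounded_rect(pts[, 1], pts[, 2], w, dpt, spec$corner_radius_mm)
  height <- th + pmax(pts[, 1], 0) * tan(alpha)
  bone <- inside2d & pts[, 3] >= 0 & pts[, 3] < height
  # sclerotic patch: contiguous blob on the distal face (z slab [0, spacing)),
  # grown from the posterior-central corner, exact pixel count
  distal <- bone & pts[, 3] >= 0 & pts[, 3] < sp
  n_distal <- sum(distal)
  n_scl <- round(spec$sclerotic_fraction * n_distal)
  scl <- logical(nrow(pts))
  if (n_scl > 0) {
    idx <- which(distal)
    d2 <- (pts[idx, 1] - 0)^2 + (pts[idx, 2] - 0)^2
    scl[idx[order(d2)[seq_len(n_scl)]]] <- TRUE
  }
  grey <- rep(spec$grey_background, nrow(pts))
  grey[bone] <- spec$grey_spongious
  grey[scl] <- spec$grey_sclerotic
  arr <- array(grey, c(nx, ny, nz))
  crop_box <- bounding_box(c(1, 1, 1), c(nx, ny, nz))
  if (spec$container) {
    # container wall: two-voxel slab at the high-AP border, outside the bone
    arr[, (ny - 1):ny, ] <- spec$grey_cortical
    crop_box <- bounding_box(c(1, 1, 1), c(nx, ny - 2L, nz))
  }
  if (spec$noise_sd > 0) {
    noise <- with_seed(spec$seed, rnorm(length(arr), 0, spec$noise_sd))
    arr <- arr + array(noise, dim(arr))
  }
  vol <- volume_image(arr, rep(sp, 3), origin, c("ML", "AP", "PD"))
  area <- rounded_rect_area(w, dpt, spec$corner_radius_mm)
  prism_mm3 <- area * th + tan(alpha) * area * (w / 2)
  exp_mm <- c(medial = w * tan(alpha), central = (w / 2) * tan(alpha))
  truth <- list(
    bone_voxels = sum(bone),
    prism_mm3 = prism_mm3,
    footprint_area_mm2 = area,
    expected_max_mm = exp_mm,
    expected_max_voxel = exp_mm / sp,
    sclerotic_fraction = if (n_distal > 0) n_scl / n_distal else 0,
    # transform mapping the tilted specimen back to its untilted frame
    tilt = {
      Rb <- rotation_about_axis(c(0, 1, 0), -spec$tilt_deg)
      rigid_transform(Rb, ctr - as.vector(Rb %*% ctr))
    },
    distal_slice_index = m + ceiling(zpad / sp) + 1L,
    crop_box = crop_box
  )
  list(volume = vol, truth = truth)
}

#' Generate a synthetic sclerosis slice with exact ground truth
#'
#' A 2D disc-shaped specimen cross-section whose pixels are drawn from two
#' seeded Gaussian grey populations (spongious and sclerotic); exactly
#' `round(fraction * mask size)` pixels are sclerotic, placed as one
#' contiguous blob.
#'
#' @param spec a [phantom_spec()]; uses the grey levels, noise, sclerotic
#'   fraction and seed.
#' @param n_pixels approximate number of in-mask pixels.
#' @return list with `slice` (2D grey matrix), `slice_mask` (2D logical)
#'   and `true_fraction` (exact sclerotic pixel share).
#' @export
make_sclerosis_slice <- function(spec, n_pixels = 10000L) {
  stopifnot(inherits(spec, "phantom_spec"))
  r <- sqrt(n_pixels / pi)
  n <- 2L * ceiling(r) + 5L
  cx <- (n + 1) / 2
  xy <- expand.grid(i = seq_len(n), j = seq_len(n))
  mask <- matrix((xy$i - cx)^2 + (xy$j - cx)^2 <= r^2, n, n)
  n_mask <- sum(mask)
  n_scl <- round(spec$sclerotic_fraction * n_mask)
  idx <- which(mask)
  # contiguous blob nearest the mask's left edge
  ii <- ((idx - 1) %% n) + 1
  jjj <- ((idx - 1) %/% n) + 1
  d2 <- (ii - 1)^2 + (jjj - cx)^2
  scl <- logical(length(idx))
  scl[order(d2)[seq_len(n_scl)]] <- TRUE
  slice <- matrix(spec$grey_background, n, n)
  vals <- with_seed(spec$seed + 1L, {
    base <- ifelse(scl, spec$grey_sclerotic, spec$grey_spongious)
    base + rnorm(length(base), 0, spec$noise_sd)
  })
  slice[idx] <- vals
  list(slice = slice, slice_mask = mask,
       true_fraction = if (n_mask > 0) n_scl / n_mask else 0)
}

#' Generate a two-group phantom cohort
#'
#' `n_per_group` specimens per group with deterministic per-specimen
#' jitter: footprint dimensions and thickness vary by +/-5% (uniform), and
#' each specimen gets an independent sub-seed derived from `seed`.  Group
#' truths differ in wedge angle only.  Following the clinical convention, a
#' 0-degree saw cut on a varus joint line yields the wedge-shaped specimen
#' and a 3-degree varus cut the rectangular one, so `spec_0deg` should
#' carry the positive wedge angle.
#'
#' @param n_per_group specimens per group (>= 1).
#' @param spec_0deg,spec_3deg [phantom_spec()] templates for the two
#'   groups.
#' @param seed master seed; sub-seeds are drawn deterministically from it.
#' @return list of specimen entries: `id`, `group` (`"0deg"` / `"3deg"`),
#'   `spec`, `volume`, `implant`, `truth`.
#' @export
make_cohort <- function(n_per_group, spec_0deg, spec_3deg, seed = 1L) {
  stopifnot(inherits(spec_0deg, "phantom_spec"), inherits(spec_3deg, "phantom_spec"))
  if (n_per_group < 1) rf_stop("synth", "n_per_group must be >= 1")
  subseeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L,
                                         2L * n_per_group))
  jitters <- with_seed(seed + 1L, matrix(runif(6L * n_per_group, 0.95, 1.05),
                                         ncol = 3))
  out <- vector("list", 2L * n_per_group)
  for (q in seq_len(2L * n_per_group)) {
    grp <- if (q <= n_per_group) "0deg" else "3deg"
    template <- if (grp == "0deg") spec_0deg else spec_3deg
    jit <- jitters[q, ]
    spec <- template
    spec$ml_width <- template$ml_width * jit[1]
    spec$ap_depth <- template$ap_depth * jit[2]
    spec$thickness_mm <- template$thickness_mm * jit[3]
    spec$seed <- subseeds[q]
    phant <- make_resection_volume(spec)
    out[[q]] <- list(
      id = sprintf("%s_%02d", grp, ((q - 1L) %% n_per_group) + 1L),
      group = grp, spec = spec, volume = phant$volume,
      implant = make_implant_mesh(spec), truth = phant$truth
    )
  }
  out
}
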