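#' Rotation-correct a specimen volume to its distal cut plane
#'
#' The distal cut face of the specimen is rarely exactly perpendicular to
#' the scan's proximal-distal axis.  This fits a least-squares plane to the
#' distal surface voxels of the mask (mask voxels whose distal neighbour is
#' background) and resamples volume and mask so the fitted plane normal
#' aligns with the PD axis.  Grey values are interpolated trilinearly, the
#' mask by nearest neighbour.
#'
#' @param vol a [volume_image()].
#' @param mask the one-piece specimen [binary_mask()] (same grid).
#' @return list with elements `volume`, `mask` (resampled), `angle_deg`
#'   (applied correction) and `rotation` (3 x 3 matrix, world frame).
#' @export
rotation_correct <- function(vol, mask) {
  stopifnot(inherits(vol, "volume_image"), inherits(mask, "binary_mask"))
  if (!identical(dim(vol$data), dim(mask$data)))
    rf_stop("sclerosis", "volume and mask dimensions differ")
  ipd <- axis_index(vol, "PD")
  d <- dim(mask$data)
  m <- mask$data
  # distal neighbour = one step toward lower PD index
  shifted <- array(FALSE, d)
  idx_hi <- seq_len(d[ipd])[-1]
  idx_lo <- seq_len(d[ipd] - 1L)
  pick <- function(a, which_idx) {
    sel <- rep(list(quote(expr = )), 3)
    sel[[ipd]] <- which_idx
    do.call(`[`, c(list(a), sel, list(drop = FALSE)))
  }
  assign_slices <- function(a, which_idx, value) {
    sel <- rep(list(quote(expr = )), 3)
    sel[[ipd]] <- which_idx
    do.call(`[<-`, c(list(a), sel, list(value)))
  }
  inner_distal_bg <- pick(m, idx_hi) & !pick(m, idx_lo)
  shifted <- assign_slices(shifted, idx_hi, inner_distal_bg)
  # mask voxels in the first (most distal) slice are distal-surface too
  first_sel <- rep(list(quote(expr = )), 3)
  first_sel[[ipd]] <- 1L
  shifted <- assign_slices(shifted, 1L, do.call(`[`, c(list(m), first_sel,
                                                       list(drop = FALSE))))
  surf <- which(shifted, arr.ind = TRUE)
  if (nrow(surf) < 16L)
    rf_stop("sclerosis", "only %d distal surface voxels; plane fit needs >= 16",
            nrow(surf))
  # world coordinates of surface voxels
  pts <- sweep(sweep(surf - 1, 2, vol$spacing, "*"), 2, vol$origin, "+")
  ctr <- colMeans(pts)
  sv <- svd(sweep(pts, 2, ctr))
  normal <- sv$v[, 3]
  pd_dir <- c(0, 0, 0)
  pd_dir[ipd] <- 1 # distal face normal should point along -PD (distal), so
  if (sum(normal * pd_dir) > 0) normal <- -normal
  target <- -pd_dir
  ct <- sum(normal * target)
  angle <- acos(max(-1, min(1, ct))) * 180 / pi
  if (angle < 1e-6) {
    return(list(volume = vol, mask = mask, angle_deg = 0, rotation = diag(3)))
  }
  ax <- c(normal[2] * target[3] - normal[3] * target[2],
          normal[3] * target[1] - normal[1] * target[3],
          normal[1] * target[2] - normal[2] * target[1])
  ax_n <- sqrt(sum(ax^2))
  R <- if (ax_n < 1e-12) diag(3) else rotation_about_axis(ax / ax_n, angle)
  out <- resample_rotated(vol, mask, R, ctr)
  list(volume = out$volume, mask = out$mask, angle_deg = angle, rotation = R)
}

# rotate vol+mask about world-point `center` by R, resample on the original
# grid (trilinear grey / nearest-neighbour mask)
resample_rotated <- function(vol, mask, R, center) {
  d <- dim(vol$data)
  g <- expand.grid(i = seq_len(d[1]), j = seq_len(d[2]), k = seq_len(d[3]))
  world <- sweep(sweep(as.matrix(g) - 1, 2, vol$spacing, "*"), 2, vol$origin, "+")
  # output voxel x receives the value at R^-1 (x - c) + c
  src <- sweep(sweep(world, 2, center) %*% R, 2, center, "+")
  sidx <- sweep(sweep(src, 2, vol$origin), 2, vol$spacing, "/") # 0-based frac
  lo <- floor(sidx)
  fr <- sidx - lo
  val <- numeric(nrow(sidx))
  msk <- logical(nrow(sidx))
  inb <- lo[, 1] >= 0 & lo[, 2] >= 0 & lo[, 3] >= 0 &
    lo[, 1] <= d[1] - 2 & lo[, 2] <= d[2] - 2 & lo[, 3] <= d[3] - 2
  at <- function(di, dj, dk) {
    ii <- lo[inb, 1] + di + 1; jj <- lo[inb, 2] + dj + 1; kk <- lo[inb, 3] + dk + 1
    vol$data[cbind(ii, jj, kk)]
  }
  w <- function(di, dj, dk) {
    wi <- if (di == 0) 1 - fr[inb, 1] else fr[inb, 1]
    wj <- if (dj == 0) 1 - fr[inb, 2] else fr[inb, 2]
    wk <- if (dk == 0) 1 - fr[inb, 3] else fr[inb, 3]
    wi * wj * wk
  }
  acc <- 0
  for (di in 0:1) for (dj in 0:1) for (dk in 0:1)
    acc <- acc + w(di, dj, dk) * at(di, dj, dk)
  val[inb] <- acc
  nn <- round(sidx)
  nn_in <- nn[, 1] >= 0 & nn[, 2] >= 0 & nn[, 3] >= 0 &
    nn[, 1] <= d[1] - 1 & nn[, 2] <= d[2] - 1 & nn[, 3] <= d[3] - 1
  msk[nn_in] <- mask$data[cbind(nn[nn_in, 1] + 1, nn[nn_in, 2] + 1,
                                nn[nn_in, 3] + 1)]
  list(volume = volume_image(array(val, d), vol$spacing, vol$origin, vol$axes),
       mask = mask_like(mask, array(msk, d)))
}

#' Extract the most distal axial slice of the specimen
#'
#' Returns the most distal slice (lowest PD index) whose in-mask area is at
#' least `min_area_fraction` of the maximal per-slice area -- a guard
#' against a ragged, partially filled last slice.
#'
#' @param vol rotation-corrected [volume_image()].
#' @param mask rotation-corrected specimen [binary_mask()].
#' @param min_area_fraction fraction of the maximal per-slice mask area the
#'   chosen slice must reach (default 0.5).
#' @return list with `slice` (2D grey matrix), `slice_mask` (2D logical)
#'   and `index` (PD slice index, 1 = most distal).
#' @export
most_distal_slice <- function(vol, mask, min_area_fraction = 0.5) {
  stopifnot(inherits(vol, "volume_image"), inherits(mask, "binary_mask"))
  if (!any(mask$data)) rf_stop("sclerosis", "empty mask")
  ipd <- axis_index(vol, "PD")
  areas <- apply(mask$data, ipd, sum)
  need <- min_area_fraction * max(areas)
  idx <- which(areas >= need)[1]
  sel <- rep(list(quote(expr = )), 3)
  sel[[ipd]] <- idx
  slice <- do.call(`[`, c(list(vol$data), sel))
  smask <- do.call(`[`, c(list(mask$data), sel))
  list(slice = slice, slice_mask = smask, index = idx)
}

#' Sclerosis grey-value cut-off ("upper third of the grey values")
#'
#' With the default range rule, the cut-off sits at
#' `min + fraction * (max - min)` of the in-mask grey values of the
#' analysed slice (default fraction 2/3, so the upper third is sclerotic).
#' With the quantile rule, it sits at the `fraction` quantile of in-mask
#' pixel values.  The rule is range-relative, so the resulting percentage
#' is invariant to affine rescaling of grey values.
#'
#' @param slice 2D grey matrix.
#' @param slice_mask 2D logical matrix.
#' @param fraction cut-off position in (0, 1); default 2/3.
#' @param rule `"range"` (default) or `"quantile"`.
#' @return the threshold grey value; pixels `>=` threshold count as
#'   sclerotic.
#' @export
sclerosis_threshold <- function(slice, slice_mask, fraction = 2 / 3,
                                rule = c("range", "quantile")) {
  rule <- match.arg(rule)
  if (fraction <= 0 || fraction >= 1)
    rf_stop("sclerosis", "fraction must lie in (0, 1)")
  vals <- slice[slice_mask]
  if (length(vals) == 0) rf_stop("sclerosis", "empty slice mask")
  if (length(unique(vals)) < 2L)
    rf_stop("sclerosis", "constant in-mask grey values: cut-off undefined")
  if (rule == "range") min(vals) + fraction * (max(vals) - min(vals))
  else unname(quantile(vals, fraction, type = 7))
}

# Otsu-style two-class separation of a grey sample: between-class mean gap
# in units of the pooled within-class standard deviation.  A unimodal
# Gaussian forced into two classes separates by ~2.7 of its own sd; two
# populations several noise-sd apart separate by far more, so the statistic
# distinguishes "sclerotic class present" from "noise only" with a wide
# margin on either side of the default cut of 4.
grey_class_separation <- function(vals) {
  rng <- range(vals)
  if (rng[1] == rng[2]) return(0)
  cand <- unique(stats::quantile(vals, seq(0.02, 0.98, length.out = 128),
                                 names = FALSE))
  n <- length(vals)
  best <- -Inf
  split <- cand[1]
  for (t in cand) {
    lo <- vals < t
    nl <- sum(lo)
    if (nl < 2 || n - nl < 2) next
    w <- nl / n
    bc <- w * (1 - w) * (mean(vals[lo]) - mean(vals[!lo]))^2
    if (bc > best) { best <- bc; split <- t }
  }
  lo <- vals < split
  if (sum(lo) < 2 || sum(!lo) < 2) return(0)
  a <- vals[lo]; b <- vals[!lo]
  sw <- sqrt((sum((a - mean(a))^2) + sum((b - mean(b))^2)) / (n - 2))
  if (sw == 0) return(Inf)
  (mean(b) - mean(a)) / sw
}

#' Percent sclerotic bone in a slice
#'
#' Counts in-mask pixels at or above the cut-off (sclerotic) versus below
#' (spongious); percentage = sclerotic / (sclerotic + spongious) x 100.
#'
#' The range-relative cut-off rule presumes a sclerotic grey class exists;
#' on a slice with no sclerosis it would land in the upper noise tail of
#' the single spongious population and misreport its tail mass.  The
#' default guard therefore checks two-class separability of the in-mask
#' greys (see the separation statistic in the details) and reports 0%
#' when no distinct high-grey class is present.
#'
#' @param slice 2D grey matrix.
#' @param slice_mask 2D logical matrix (non-empty).
#' @param threshold grey cut-off, e.g. from [sclerosis_threshold()].
#' @param slice_index optional slice index recorded in the result.
#' @param guard require a separable high-grey class before counting
#'   (default `TRUE`); `min_separation` is the separation cut in pooled
#'   within-class standard deviations.
#' @param min_separation see `guard`.
#' @return an object of class `sclerosis_result`: `sclerotic`, `spongious`
#'   (pixel counts), `percent`, `threshold`, `slice_index`.
#' @export
sclerosis_percent <- function(slice, slice_mask, threshold,
                              slice_index = NA_integer_, guard = TRUE,
                              min_separation = 4) {
  vals <- slice[slice_mask]
  if (length(vals) == 0) rf_stop("sclerosis", "empty slice mask")
  if (threshold > max(vals))
    warning("threshold above the in-mask maximum: 0% sclerosis")
  scl <- sum(vals >= threshold)
  if (guard && scl > 0 && length(vals) > 4 &&
      grey_class_separation(vals) < min_separation) {
    rf_log("info", "no separable sclerotic grey class; reporting 0%%")
    scl <- 0L
  }
  spo <- length(vals) - scl
  structure(list(sclerotic = as.integer(scl), spongious = as.integer(spo),
                 percent = 100 * scl / (scl + spo), threshold = threshold,
                 slice_index = as.integer(slice_index)),
            class = "sclerosis_result")
}

#' @export
print.sclerosis_result <- function(x, ...) {
  cat(sprintf("<sclerosis_result> %.1f%% sclerotic (%d / %d pixels) at cut-off %.4g\n",
              x$percent, x$sclerotic, x$sclerotic + x$spongious, x$threshold))
  invisible(x)
}
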