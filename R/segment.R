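#' Threshold a volume into a binary mask
#'
#' Voxels with `low <= value < high` become foreground (half-open band, so
#' stacked bands never double-count a voxel).  Raising `low` never adds
#' voxels.
#'
#' @param vol a [volume_image()].
#' @param low lower grey value (inclusive).
#' @param high upper grey value (exclusive); default `Inf`.
#' @return a [binary_mask()].  An empty result is allowed but logged as a
#'   warning.
#' @export
threshold_mask <- function(vol, low, high = Inf) {
  stopifnot(inherits(vol, "volume_image"))
  if (!is.finite(low) || low >= high)
    rf_stop("segment", "need low < high (got %g, %g)", low, high)
  m <- vol$data >= low & vol$data < high
  if (!any(m)) warning("threshold produced an empty mask")
  mask_like(vol, array(m, dim(vol$data)))
}

#' Otsu's threshold of a grey-value volume
#'
#' Automated stand-in for an interactive threshold choice: the grey value
#' maximising the between-class variance of the histogram, computed over the
#' whole volume or a region mask.  Thresholding at the returned value with
#' [threshold_mask()] separates the two classes (foreground is `>=`).
#'
#' @param vol a [volume_image()].
#' @param mask optional [binary_mask()] restricting the histogram domain.
#' @param nbins number of histogram bins.
#' @return the threshold grey value.
#' @export
otsu_threshold <- function(vol, mask = NULL, nbins = 256L) {
  stopifnot(inherits(vol, "volume_image"))
  vals <- if (is.null(mask)) as.vector(vol$data) else vol$data[mask$data]
  rng <- range(vals)
  if (rng[1] == rng[2])
    rf_stop("segment", "constant grey values: Otsu threshold undefined")
  edges <- seq(rng[1], rng[2], length.out = nbins + 1L)
  h <- tabulate(pmin(findInterval(vals, edges, rightmost.closed = TRUE), nbins),
                nbins)
  p <- h / sum(h)
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * centers)
  mu_t <- mu[nbins]
  valid <- w0 > 0 & w0 < 1
  sigma_b <- rep(-Inf, nbins)
  sigma_b[valid] <- (mu_t * w0[valid] - mu[valid])^2 /
    (w0[valid] * (1 - w0[valid]))
  # an empty valley between two classes yields a plateau of exactly tied
  # criteria; average the tied bins (classic tie handling) so the threshold
  # sits mid-valley rather than at its left edge
  k <- which(sigma_b == max(sigma_b))
  mean(edges[k + 1L])
}

#' Crop a volume to a bounding box
#'
#' Returns the sub-volume; the world origin shifts so voxel world positions
#' are preserved.
#'
#' @param vol a [volume_image()] or [binary_mask()].
#' @param box a [bounding_box()] within the volume bounds.
#' @return the cropped object, same class as `vol`.
#' @export
crop <- function(vol, box) {
  stopifnot(inherits(box, "bounding_box"))
  d <- dim(vol$data)
  if (any(box$upper > d))
    rf_stop("segment", "bounding box exceeds volume extent %s",
            paste(d, collapse = "x"))
  idx <- Map(seq, box$lower, box$upper)
  sub <- vol$data[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  new_origin <- vol$origin + (box$lower - 1) * vol$spacing
  if (inherits(vol, "binary_mask"))
    binary_mask(sub, vol$spacing, new_origin, vol$axes)
  else
    volume_image(sub, vol$spacing, new_origin, vol$axes)
}

#' Keep only the largest connected component
#'
#' The physical specimen is removed in one piece; this enforces the same
#' digitally, dropping disconnected débris and noise specks.  Size ties are
#' broken in favour of the component whose minimal voxel index is
#' lexicographically smallest.
#'
#' @param mask a non-empty [binary_mask()].
#' @param connectivity 6 (faces) or 26 (faces, edges, corners; default --
#'   most permissive, appropriate for one-piece specimens).
#' @return the filtered [binary_mask()].
#' @export
largest_component <- function(mask, connectivity = 26L) {
  stopifnot(inherits(mask, "binary_mask"))
  if (!connectivity %in% c(6L, 26L))
    rf_stop("segment", "connectivity must be 6 or 26")
  if (!any(mask$data)) rf_stop("segment", "empty mask")
  lab <- cpp_label_components(mask$data, dim(mask$data), as.integer(connectivity))
  sizes <- tabulate(lab[lab > 0L])
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {
    # lexicographic (i, j, k) minimal index per tied component
    keys <- lapply(best, function(l) {
      w <- which(lab == l, arr.ind = TRUE)
      w[order(w[, 1], w[, 2], w[, 3])[1], ]
    })
    ord <- do.call(order, as.data.frame(do.call(rbind, keys)))
    best <- best[ord[1]]
  }
  mask_like(mask, array(lab == best, dim(mask$data)))
}

#' Voxel count and physical volume of a mask
#'
#' @param mask a [binary_mask()].
#' @return list with `voxels` (count) and `mm3`
#'   (count x voxel volume).
#' @export
mask_volume <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  n <- sum(mask$data)
  list(voxels = as.integer(n), mm3 = n * prod(mask$spacing))
}
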