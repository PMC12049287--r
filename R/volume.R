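#' Volumetric grey-value image
#'
#' Container for a 3D scalar grid with physical voxel spacing, world origin
#' and anatomical axis labels.  The world position of voxel centre
#' `(i, j, k)` (1-based R indices) is `origin + (c(i, j, k) - 1) * spacing`,
#' in millimetres, in a right-handed frame.
#'
#' Axis labels name what each array axis runs along:
#' \describe{
#'   \item{`"ML"`}{medial--lateral; coordinate increases towards medial.}
#'   \item{`"AP"`}{anterior--posterior; coordinate increases towards anterior.}
#'   \item{`"PD"`}{proximal--distal; coordinate increases towards proximal,
#'     so slice 1 along this axis is the most distal.}
#' }
#'
#' @param data numeric 3D array of grey values.
#' @param spacing numeric length-3, mm per voxel along each array axis; all
#'   positive.
#' @param origin numeric length-3, world position (mm) of the first voxel
#'   centre.
#' @param axes character length-3 permutation of `c("ML", "AP", "PD")`
#'   labelling the array axes.
#' @return an object of class `volume_image`.
#' @export
volume_image <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                         axes = c("ML", "AP", "PD")) {
  if (!is.array(data) || length(dim(data)) != 3L)
    rf_stop("volume", "data must be a 3D array")
  if (any(dim(data) < 2L))
    rf_stop("volume", "each axis must have at least 2 voxels (got %s)",
            paste(dim(data), collapse = "x"))
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    rf_stop("volume", "spacing must be 3 positive finite numbers")
  if (length(origin) != 3L || any(!is.finite(origin)))
    rf_stop("volume", "origin must be 3 finite numbers")
  axes <- as.character(axes)
  if (length(axes) != 3L || !setequal(axes, c("ML", "AP", "PD")) ||
      anyDuplicated(axes))
    rf_stop("volume", "axes must be a permutation of ML, AP, PD")
  structure(list(data = data, spacing = spacing, origin = origin, axes = axes),
            class = "volume_image")
}

#' @export
print.volume_image <- function(x, ...) {
  cat(sprintf("<volume_image> %s voxels, spacing %s mm, axes %s\n",
              paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              paste(x$axes, collapse = ",")))
  cat(sprintf("  grey range [%g, %g], origin (%s) mm\n",
              min(x$data), max(x$data),
              paste(signif(x$origin, 4), collapse = ", ")))
  invisible(x)
}

#' @export
dim.volume_image <- function(x) dim(x$data)

# index of the array axis carrying an anatomical label
axis_index <- function(x, label) {
  i <- match(label, x$axes)
  if (is.na(i)) rf_stop("volume", "no axis labelled %s", label)
  i
}

#' Binary segmentation mask
#'
#' A logical 3D array sharing spacing/origin/axes with its source volume.
#'
#' @param data logical 3D array.
#' @param spacing,origin,axes geometry inherited from the source
#'   [volume_image()].
#' @return an object of class `binary_mask`.
#' @export
binary_mask <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                        axes = c("ML", "AP", "PD")) {
  if (!is.array(data) || length(dim(data)) != 3L)
    rf_stop("mask", "data must be a 3D logical array")
  storage.mode(data) <- "logical"
  v <- volume_image(array(0, dim(data)), spacing, origin, axes) # geometry checks
  structure(list(data = data, spacing = v$spacing, origin = v$origin,
                 axes = v$axes),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %s voxels, %d foreground (%.1f%%)\n",
              paste(dim(x$data), collapse = "x"), sum(x$data),
              100 * mean(x$data)))
  invisible(x)
}

# mask with geometry copied from a volume/mask
mask_like <- function(src, data) {
  binary_mask(data, src$spacing, src$origin, src$axes)
}

#' Axis-aligned voxel bounding box
#'
#' Inclusive 1-based index ranges per array axis, `lower[d] <= upper[d]`.
#'
#' @param lower,upper integer length-3 voxel indices (1-based, inclusive).
#' @return an object of class `bounding_box`.
#' @export
bounding_box <- function(lower, upper) {
  lower <- as.integer(lower); upper <- as.integer(upper)
  if (length(lower) != 3L || length(upper) != 3L || anyNA(lower) || anyNA(upper))
    rf_stop("crop", "bounding box needs two integer index triples")
  if (any(lower < 1L)) rf_stop("crop", "lower indices must be >= 1")
  if (any(lower > upper)) rf_stop("crop", "lower must not exceed upper")
  structure(list(lower = lower, upper = upper), class = "bounding_box")
}
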