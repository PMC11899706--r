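#' OCT volume and ROI mask containers
#'
#' An `oct_volume` wraps a 3D array of gray values in \[0, 255\] together with
#' its physical voxel spacing (mm) and origin. An `oct_mask` wraps a binary
#' 3D array with the same geometry; any non-zero voxel is foreground.
#'
#' Index convention used throughout the package: voxel indices are 1-based in
#' R with axis order (x, y, z) = (column, row, slice); physical position of
#' voxel `(i, j, k)` is `origin + (i - 1, j - 1, k - 1) * spacing`.
#'
#' @param values 3D numeric or integer array.
#' @param spacing Numeric length-3, voxel spacing in mm, all positive.
#' @param origin Numeric length-3, physical origin in mm.
#' @return An object of class `oct_volume` or `oct_mask`: a list with
#'   elements `values`, `spacing`, `origin`.
#' @examples
#' vol <- oct_volume(array(100, c(4, 4, 2)), spacing = c(0.05, 0.05, 0.05))
#' msk <- oct_mask(array(1L, c(4, 4, 2)), spacing = c(0.05, 0.05, 0.05))
#' @export
oct_volume <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  check_geometry(values, spacing, origin)
  if (min(values, na.rm = TRUE) < 0 || max(values, na.rm = TRUE) > 255) {
    abort("oct_volume intensities must lie in [0, 255]")
  }
  structure(list(values = values, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "oct_volume")
}

#' @rdname oct_volume
#' @export
oct_mask <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  check_geometry(values, spacing, origin)
  v <- array(as.integer(values != 0), dim = dim(values))
  structure(list(values = v, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "oct_mask")
}

check_geometry <- function(values, spacing, origin) {
  if (!is.array(values) || length(dim(values)) != 3L) {
    abort("`values` must be a 3-dimensional array")
  }
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    abort("`spacing` must be 3 positive finite numbers (mm)")
  }
  if (length(origin) != 3L || any(!is.finite(origin))) {
    abort("`origin` must be 3 finite numbers (mm)")
  }
  invisible(TRUE)
}

#' @export
print.oct_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<oct_volume> %d x %d x %d voxels, spacing (%g, %g, %g) mm, range [%g, %g]\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
print.oct_mask <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<oct_mask> %d x %d x %d voxels, %d foreground, spacing (%g, %g, %g) mm\n",
              d[1], d[2], d[3], sum(x$values), x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

#' @export
dim.oct_volume <- function(x) dim(x$values)

#' @export
dim.oct_mask <- function(x) dim(x$values)

#' Check that a mask is aligned with a volume
#'
#' A mask pairs with a volume only if shapes match exactly and spacings agree;
#' ROI-consuming operations additionally require at least one foreground voxel.
#'
#' @param volume An [oct_volume()].
#' @param mask An [oct_mask()].
#' @param require_foreground Require at least one foreground voxel.
#' @return Invisibly `TRUE`; errors otherwise.
#' @export
check_alignment <- function(volume, mask, require_foreground = TRUE) {
  stopifnot(inherits(volume, "oct_volume"), inherits(mask, "oct_mask"))
  if (!identical(dim(volume$values), dim(mask$values))) {
    abort(sprintf("mask shape (%s) does not match volume shape (%s)",
                  paste(dim(mask$values), collapse = "x"),
                  paste(dim(volume$values), collapse = "x")))
  }
  if (max(abs(volume$spacing - mask$spacing)) > 1e-8) {
    abort("mask spacing does not match volume spacing")
  }
  if (require_foreground && sum(mask$values) == 0L) {
    abort("mask has no foreground voxels (empty ROI)")
  }
  invisible(TRUE)
}

#' Collapse a 3-channel monochromatic scan to grayscale
#'
#' Some OCT exports store a monochromatic scan as three identical RGB
#' channels. If all channels agree voxelwise the first channel is returned;
#' if they disagree the rounded channel mean is returned with a warning,
#' since disagreement signals corrupted data. A plain 3D input passes through
#' unchanged.
#'
#' @param values 4D array whose last axis has exactly 3 channels, or a 3D
#'   array (returned as is).
#' @return 3D array of gray values.
#' @examples
#' x <- array(42, c(2, 2, 2, 3))
#' all(rgb_to_grayscale(x) == 42)
#' @export
rgb_to_grayscale <- function(values) {
  d <- dim(values)
  if (length(d) == 3L) return(values)
  if (length(d) != 4L || d[4] != 3L) {
    abort("expected a 3D array or a 4D array with 3 channels on the last axis")
  }
  r <- values[, , , 1L]; g <- values[, , , 2L]; b <- values[, , , 3L]
  if (identical(all.equal(r, g), TRUE) && identical(all.equal(r, b), TRUE)) {
    return(array(r, dim = d[1:3]))
  }
  warn("RGB channels disagree for a monochromatic scan; returning rounded channel mean")
  array(round((r + g + b) / 3), dim = d[1:3])
}
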