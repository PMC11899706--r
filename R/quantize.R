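#' Bin-width grid of record
#'
#' The fixed-bin-size discretization sweep evaluates bin widths 5 to 50 in
#' steps of 5 (gray-value units on the 0-255 OCT scale).
#'
#' @return Integer vector of bin widths.
#' @export
bw_grid <- function() seq(5L, 50L, by = 5L)

#' Fixed-bin-size gray-level quantization of ROI intensities
#'
#' Discretizes the intensities under the mask into integer gray levels with
#' the fixed-bin-size (FBS) rule anchored at the ROI minimum:
#' `level(x) = floor((x - min_ROI) / BW) + 1`. The number of levels is
#' `Ng = floor((max_ROI - min_ROI) / BW) + 1`. Anchoring the first bin at the
#' ROI minimum makes the levels invariant to adding a constant to all ROI
#' intensities, and matches the default behaviour of the standard radiomics
#' extraction toolchain.
#'
#' @param volume An [oct_volume()].
#' @param mask An aligned [oct_mask()] with at least one foreground voxel.
#' @param bin_width Positive bin width in gray-value units.
#' @return A `quantized_roi` object: list with `levels` (3D integer array,
#'   levels 1..Ng inside the ROI, 0 outside), `ng`, `bin_width`, `anchor`
#'   (the ROI minimum), `n_voxels`, `spacing`.
#' @examples
#' vol <- oct_volume(array(c(10, 60, 0, 0), c(2, 2, 1)))
#' msk <- oct_mask(array(c(1, 1, 0, 0), c(2, 2, 1)))
#' q <- quantize_fbs(vol, msk, 50)
#' q$ng  # 2
#' @export
quantize_fbs <- function(volume, mask, bin_width) {
  check_alignment(volume, mask)
  if (!is.numeric(bin_width) || length(bin_width) != 1L || !is.finite(bin_width) ||
      bin_width <= 0) {
    abort("`bin_width` must be a single positive number")
  }
  # crop to the mask bounding box: every texture matrix involves only ROI
  # voxels, so the surrounding empty volume is irrelevant
  idx <- which(mask$values != 0L, arr.ind = TRUE)
  lo <- apply(idx, 2, min); hi <- apply(idx, 2, max)
  mv <- mask$values[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  vv <- volume$values[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  inroi <- mv != 0L
  x <- vv[inroi]
  anchor <- min(x)
  lev <- array(0L, dim = dim(mv))
  lev[inroi] <- as.integer(floor((x - anchor) / bin_width)) + 1L
  ng <- as.integer(floor((max(x) - anchor) / bin_width)) + 1L
  structure(list(levels = lev, ng = ng, bin_width = bin_width, anchor = anchor,
                 n_voxels = sum(inroi), spacing = volume$spacing),
            class = "quantized_roi")
}

#' @export
print.quantized_roi <- function(x, ...) {
  cat(sprintf("<quantized_roi> %d ROI voxels, BW = %g, Ng = %d (anchor %g)\n",
              x$n_voxels, x$bin_width, x$ng, x$anchor))
  invisible(x)
}
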