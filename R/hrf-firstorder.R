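#' First-order intensity features
#'
#' The 18 standard first-order statistics of the ROI intensity distribution.
#' `Entropy` and `Uniformity` are computed on the fixed-bin-size discretized
#' histogram at the given bin width; all other features use the raw gray
#' values. Conventions: population moments throughout; `Energy` is the plain
#' sum of squares (no intensity shift); `TotalEnergy` multiplies by the voxel
#' volume in mm^3; `Skewness`/`Kurtosis` are the standardized third and
#' fourth moments (kurtosis not excess-corrected) and are defined as 0 for a
#' constant ROI; `RobustMeanAbsoluteDeviation` is the mean absolute
#' deviation of the values inside the 10th-90th percentile range.
#'
#' @param volume An [oct_volume()].
#' @param mask An aligned, non-empty [oct_mask()].
#' @param bin_width Bin width for the discretized histogram.
#' @return Named numeric vector of 18 features prefixed `firstorder_`.
#' @export
first_order_features <- function(volume, mask, bin_width) {
  check_alignment(volume, mask)
  x <- volume$values[mask$values != 0L]
  n <- length(x)
  voxvol <- prod(volume$spacing)
  q <- quantize_fbs(volume, mask, bin_width)
  p <- tabulate(q$levels[q$levels > 0L], nbins = q$ng) / n
  eps <- .Machine$double.eps

  m <- mean(x)
  m2 <- mean((x - m)^2)
  m3 <- mean((x - m)^3)
  m4 <- mean((x - m)^4)
  pr <- quantile(x, c(0.10, 0.25, 0.75, 0.90), names = FALSE)
  xr <- x[x >= pr[1] & x <= pr[4]]

  c(firstorder_Energy = sum(x^2),
    firstorder_TotalEnergy = voxvol * sum(x^2),
    firstorder_Entropy = -sum(p * log2(p + eps)),
    firstorder_Minimum = min(x),
    firstorder_Percentile10 = pr[1],
    firstorder_Percentile90 = pr[4],
    firstorder_Maximum = max(x),
    firstorder_Mean = m,
    firstorder_Median = median(x),
    firstorder_InterquartileRange = pr[3] - pr[2],
    firstorder_Range = max(x) - min(x),
    firstorder_MeanAbsoluteDeviation = mean(abs(x - m)),
    firstorder_RobustMeanAbsoluteDeviation = mean(abs(xr - mean(xr))),
    firstorder_RootMeanSquared = sqrt(mean(x^2)),
    firstorder_Skewness = if (m2 > 0) m3 / m2^1.5 else 0,
    firstorder_Kurtosis = if (m2 > 0) m4 / m2^2 else 0,
    firstorder_Variance = m2,
    firstorder_Uniformity = sum(p^2))
}
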