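#' Extract the full handcrafted feature vector for one ROI
#'
#' Concatenates all seven feature families — 18 first-order, 14 shape, 24
#' GLCM, 16 GLRLM, 16 GLSZM, 14 GLDM and 5 NGTDM features — into one named
#' vector of exactly 107 values. Texture families consume the fixed-bin-size
#' quantization at `bin_width`; shape features ignore intensities entirely
#' and are identical for every bin width.
#'
#' @param volume An [oct_volume()].
#' @param mask An aligned, non-empty [oct_mask()].
#' @param bin_width Quantization bin width.
#' @return Named numeric vector of length 107.
#' @examples
#' params <- lesion_class_params("nevus", ellipsoid_semi_axes = c(0.5, 0.4, 0.3))
#' scan <- generate_lesion_volume(params, shape = c(48, 48, 32), seed = 1)
#' fv <- extract_feature_vector(scan$volume, scan$mask, bin_width = 25)
#' length(fv)
#' @export
extract_feature_vector <- function(volume, mask, bin_width = 25) {
  check_alignment(volume, mask)
  q <- quantize_fbs(volume, mask, bin_width)
  out <- c(first_order_features(volume, mask, bin_width),
           shape_features(mask),
           glcm_features(q),
           glrlm_features(q),
           glszm_features(q),
           gldm_features(q),
           ngtdm_features(q))
  stopifnot(length(out) == 107L)
  out
}

#' Feature name catalogue
#'
#' The 107 default feature names with their family tags, in extraction order.
#'
#' @return Tibble with columns `feature`, `family`.
#' @export
hrf_feature_names <- function() {
  tibble(feature = c(
    paste0("firstorder_",
           c("Energy", "TotalEnergy", "Entropy", "Minimum", "Percentile10",
             "Percentile90", "Maximum", "Mean", "Median", "InterquartileRange",
             "Range", "MeanAbsoluteDeviation", "RobustMeanAbsoluteDeviation",
             "RootMeanSquared", "Skewness", "Kurtosis", "Variance",
             "Uniformity")),
    paste0("shape_",
           c("MeshVolume", "VoxelVolume", "SurfaceArea", "SurfaceVolumeRatio",
             "Sphericity", "Maximum3DDiameter", "Maximum2DDiameterSlice",
             "Maximum2DDiameterColumn", "Maximum2DDiameterRow",
             "MajorAxisLength", "MinorAxisLength", "LeastAxisLength",
             "Elongation", "Flatness")),
    paste0("glcm_", glcm_feature_names()),
    paste0("glrlm_", glrlm_feature_names()),
    paste0("glszm_", glszm_feature_names()),
    paste0("gldm_", gldm_feature_names()),
    paste0("ngtdm_", c("Coarseness", "Contrast", "Busyness", "Complexity",
                       "Strength")))) |>
    dplyr::mutate(family = sub("_.*$", "", .data$feature))
}

#' Extract a long feature table over scans and bin widths
#'
#' Runs [extract_feature_vector()] for every scan at every bin width and
#' returns a tidy long table. Scans can come from a synthetic cohort
#' (rendered lazily, one at a time) or from a list of
#' `list(scan_id =, volume =, mask =)` entries.
#'
#' @param x An `oct_cohort` from [generate_study_cohorts()], or a list of
#'   scans.
#' @param bin_widths Bin widths to evaluate; each is applied exactly once per
#'   scan. Default [bw_grid()].
#' @param scan_ids For a cohort, subset of scan ids (default: all).
#' @return Tibble with columns `scan_id`, `bw`, `feature`, `value`.
#' @export
extract_features <- function(x, bin_widths = bw_grid(), scan_ids = NULL) {
  if (any(duplicated(bin_widths))) abort("`bin_widths` must not contain duplicates")
  if (inherits(x, "oct_cohort")) {
    ids <- scan_ids %||% x$manifest$scan_id
    get_scan <- function(id) render_scan(x, id)
  } else if (is.list(x)) {
    ids <- vapply(x, function(s) s$scan_id, character(1))
    names(x) <- ids
    get_scan <- function(id) x[[id]]
  } else {
    abort("`x` must be an oct_cohort or a list of scans")
  }
  purrr::map_dfr(ids, function(id) {
    scan <- get_scan(id)
    check_alignment(scan$volume, scan$mask)
    # shape features take no intensity input: compute once per scan
    sf <- shape_features(scan$mask)
    purrr::map_dfr(bin_widths, function(bw) {
      q <- quantize_fbs(scan$volume, scan$mask, bw)
      fv <- c(first_order_features(scan$volume, scan$mask, bw), sf,
              glcm_features(q), glrlm_features(q), glszm_features(q),
              gldm_features(q), ngtdm_features(q))
      tibble(scan_id = id, bw = bw, feature = names(fv), value = unname(fv))
    })
  })
}

#' Pivot a long feature table to a scans-by-features matrix
#'
#' @param features Long table from [extract_features()].
#' @param bw Single bin width to select.
#' @return Tibble with one row per `scan_id` and one column per feature.
#' @export
features_wide <- function(features, bw) {
  stopifnot(length(bw) == 1L)
  features |>
    dplyr::filter(.data$bw == !!bw) |>
    dplyr::select("scan_id", "feature", "value") |>
    tidyr::pivot_wider(names_from = "feature", values_from = "value")
}
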