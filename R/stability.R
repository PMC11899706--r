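#' Lin's concordance correlation coefficient
#'
#' Agreement between two paired measurement vectors:
#' `CCC = 2 * rho * s1 * s2 / (s1^2 + s2^2 + (m1 - m2)^2)` with means `m`,
#' population standard deviations `s` and Pearson correlation `rho`. Ranges
#' from -1 (inverse concordance) through 0 (no concordance) to 1 (perfect
#' agreement); symmetric in its arguments, and equal to 1 only when `x == y`
#' with non-zero variance. When both vectors are constant agreement is
#' unmeasurable and `NA` is returned.
#'
#' @param x,y Equal-length numeric vectors with at least 3 pairs.
#' @return A single value in \[-1, 1\], or `NA` when both inputs are constant.
#' @examples
#' ccc(1:3, 2:4)  # 4/7
#' ccc(1:3, 3:1)  # -1
#' @export
ccc <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length")
  if (length(x) < 3L) abort("CCC requires at least 3 pairs")
  if (anyNA(x) || anyNA(y)) return(NA_real_)
  n <- length(x)
  m1 <- mean(x); m2 <- mean(y)
  v1 <- mean((x - m1)^2); v2 <- mean((y - m2)^2)
  if (v1 == 0 && v2 == 0) return(NA_real_)
  cov12 <- mean((x - m1) * (y - m2))
  2 * cov12 / (v1 + v2 + (m1 - m2)^2)
}

#' Per-feature test-retest repeatability at one bin width
#'
#' Computes one CCC per feature over all lesion pairs (test value vs retest
#' value, paired by `lesion_id`) and flags features with `CCC >= threshold`
#' (the cut is inclusive) as repeatable. Features whose CCC is undefined
#' (both vectors constant) are marked non-evaluable and never repeatable.
#'
#' @param features Long feature table from [extract_features()].
#' @param manifest Cohort manifest with columns `scan_id`, `lesion_id`,
#'   `timepoint` (1 = test, 2 = retest).
#' @param bw Bin width to evaluate.
#' @param threshold CCC repeatability cut, default 0.9.
#' @return Tibble with columns `feature`, `ccc`, `repeatable`.
#' @export
repeatability_screen <- function(features, manifest, bw, threshold = 0.9) {
  paired <- features |>
    dplyr::filter(.data$bw == !!bw) |>
    dplyr::inner_join(manifest |>
                        dplyr::select("scan_id", "lesion_id", "timepoint"),
                      by = "scan_id") |>
    dplyr::select("feature", "lesion_id", "timepoint", "value") |>
    tidyr::pivot_wider(names_from = "timepoint", values_from = "value",
                       names_prefix = "t")
  n_pairs <- length(unique(paired$lesion_id))
  if (n_pairs < 3L) abort("repeatability needs at least 3 lesion pairs")
  paired |>
    dplyr::summarise(ccc = ccc(.data$t1, .data$t2), .by = "feature") |>
    dplyr::mutate(repeatable = !is.na(.data$ccc) & .data$ccc >= threshold)
}

#' Remove redundant features by Spearman correlation
#'
#' Greedy redundancy elimination on a repeatable feature set: while any pair
#' of kept features has `|Spearman rho| >= threshold`, the pair with the
#' largest `|rho|` is examined and its member with the lower repeatability
#' CCC is dropped (ties broken towards keeping the lexicographically earlier
#' name). The result contains no pair at or above the threshold.
#'
#' @param repeatable Character vector of repeatable feature names.
#' @param values Wide scans-by-features tibble (test-scan values) from
#'   [features_wide()].
#' @param ccc_values Named numeric vector of repeatability CCCs.
#' @param threshold Spearman redundancy cut, default 0.9.
#' @return Character vector: the deduplicated feature set.
#' @export
spearman_dedup <- function(repeatable, values, ccc_values, threshold = 0.9) {
  keep <- intersect(repeatable, colnames(values))
  if (length(keep) < 2L) return(sort(keep))
  m <- as.matrix(values[, keep, drop = FALSE])
  rho <- suppressWarnings(cor(m, method = "spearman"))
  rho[is.na(rho)] <- 0
  diag(rho) <- 0
  repeat {
    a <- abs(rho[keep, keep, drop = FALSE])
    if (length(keep) < 2L || max(a) < threshold) break
    worst <- which(a == max(a), arr.ind = TRUE)[1, ]
    f1 <- keep[worst[1]]; f2 <- keep[worst[2]]
    c1 <- ccc_values[[f1]] %||% -Inf
    c2 <- ccc_values[[f2]] %||% -Inf
    drop <- if (c1 < c2) f1 else if (c2 < c1) f2 else max(f1, f2)
    keep <- setdiff(keep, drop)
  }
  sort(keep)
}

#' Cross-bin-width consistent core
#'
#' Intersection of the per-bin-width deduplicated repeatable sets, plus the
#' features specific to single bin widths.
#'
#' @param sets Named list (one element per bin width) of feature-name
#'   vectors.
#' @return List with `core` (features present at every bin width) and
#'   `per_bw_only` (named list of features unique to exactly one bin width).
#' @export
consistent_core <- function(sets) {
  if (length(sets) == 0L) return(list(core = character(), per_bw_only = list()))
  core <- sort(Reduce(intersect, sets))
  counts <- table(unlist(sets))
  only_once <- names(counts)[counts == 1L]
  per_bw_only <- lapply(sets, function(s) sort(intersect(s, only_once)))
  list(core = core, per_bw_only = per_bw_only)
}

#' Cross-bin-width reproducibility counts
#'
#' For every unordered bin-width pair, counts the features whose value
#' vectors over the same scans agree with `CCC >= threshold` between the two
#' bin widths. Shape features, being independent of binning, always agree
#' with themselves; the diagonal holds the number of evaluable (finite,
#' non-constant-pair) features at each bin width.
#'
#' @param features Long feature table from [extract_features()] covering all
#'   bin widths for the same scans.
#' @param threshold CCC reproducibility cut, default 0.9.
#' @return Tibble with columns `bw1`, `bw2`, `n_reproducible` (symmetric).
#' @export
cross_bw_reproducibility <- function(features, threshold = 0.9) {
  bws <- sort(unique(features$bw))
  wide <- features |>
    dplyr::select("scan_id", "bw", "feature", "value") |>
    tidyr::pivot_wider(names_from = "bw", values_from = "value")
  by_feature <- split(wide, wide$feature)
  out <- list()
  for (i in seq_along(bws)) for (j in i:length(bws)) {
    b1 <- as.character(bws[i]); b2 <- as.character(bws[j])
    n_rep <- sum(vapply(by_feature, function(d) {
      v <- suppressWarnings(ccc_or_identity(d[[b1]], d[[b2]]))
      !is.na(v) && v >= threshold
    }, logical(1)))
    out[[length(out) + 1L]] <- tibble(bw1 = bws[i], bw2 = bws[j],
                                      n_reproducible = n_rep)
    if (i != j) {
      out[[length(out) + 1L]] <- tibble(bw1 = bws[j], bw2 = bws[i],
                                        n_reproducible = n_rep)
    }
  }
  dplyr::bind_rows(out) |> dplyr::arrange(.data$bw1, .data$bw2)
}

# identical vectors agree perfectly even when CCC is formally undefined
# (constant features), except when values are non-finite
ccc_or_identity <- function(x, y) {
  if (any(!is.finite(x)) || any(!is.finite(y))) return(NA_real_)
  if (identical(x, y)) return(1)
  ccc(x, y)
}

#' Full stability report: repeatability, redundancy removal, core set
#'
#' Runs the complete stability screen: per bin width, the test-retest
#' repeatability of every feature (CCC over lesion pairs), redundancy
#' removal by Spearman correlation among the repeatable features, and the
#' cross-bin-width consistent core; plus the bin-width-pair reproducibility
#' counts computed from the test scans.
#'
#' @param features Long feature table covering both timepoints and all bin
#'   widths.
#' @param manifest Cohort manifest (columns `scan_id`, `lesion_id`,
#'   `timepoint`).
#' @param ccc_threshold Repeatability/reproducibility CCC cut, default 0.9.
#' @param spearman_threshold Redundancy cut, default 0.9.
#' @return A `stability_report`: list with `repeatability` (tibble: bw,
#'   feature, ccc, repeatable, kept_after_dedup), `dedup_sets` (named list),
#'   `core` (character), `per_bw_only` (named list), `reproducibility`
#'   (tibble: bw1, bw2, n_reproducible), and the thresholds.
#' @export
stability_report <- function(features, manifest, ccc_threshold = 0.9,
                             spearman_threshold = 0.9) {
  bws <- sort(unique(features$bw))
  test_ids <- manifest$scan_id[manifest$timepoint == 1L]
  rep_tabs <- list()
  dedup_sets <- list()
  for (b in bws) {
    scr <- repeatability_screen(features, manifest, b, ccc_threshold)
    wide_test <- features_wide(
      features |> dplyr::filter(.data$scan_id %in% test_ids), b)
    kept <- spearman_dedup(scr$feature[scr$repeatable], wide_test,
                           setNames(scr$ccc, scr$feature), spearman_threshold)
    scr$kept_after_dedup <- scr$feature %in% kept
    scr$bw <- b
    rep_tabs[[as.character(b)]] <- scr
    dedup_sets[[as.character(b)]] <- kept
  }
  core <- consistent_core(dedup_sets)
  repro <- cross_bw_reproducibility(
    features |> dplyr::filter(.data$scan_id %in% test_ids), ccc_threshold)
  structure(list(
    repeatability = dplyr::bind_rows(rep_tabs) |>
      dplyr::select("bw", "feature", "ccc", "repeatable", "kept_after_dedup"),
    dedup_sets = dedup_sets,
    core = core$core,
    per_bw_only = core$per_bw_only,
    reproducibility = repro,
    ccc_threshold = ccc_threshold,
    spearman_threshold = spearman_threshold),
    class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  nb <- length(unique(x$repeatability$bw))
  cat(sprintf("<stability_report> %d bin widths, %d features\n", nb,
              length(unique(x$repeatability$feature))))
  cat(sprintf("  consistent core (%d): %s\n", length(x$core),
              paste(x$core, collapse = ", ")))
  invisible(x)
}

#' @rdname stability_report
#' @param x A `stability_report`.
#' @param ... Unused.
#' @export
tidy.stability_report <- function(x, ...) x$repeatability

#' @rdname stability_report
#' @export
glance.stability_report <- function(x, ...) {
  x$repeatability |>
    dplyr::summarise(n_repeatable = sum(.data$repeatable),
                     n_kept = sum(.data$kept_after_dedup), .by = "bw") |>
    dplyr::mutate(n_core = length(x$core))
}

#' Plot repeatability CCC distributions per family and bin width
#'
#' Box plots of per-feature repeatability CCCs grouped by feature family,
#' one panel per family, across the bin-width grid.
#'
#' @param object A `stability_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.stability_report <- function(object, ...) {
  df <- object$repeatability |>
    dplyr::mutate(family = sub("_.*$", "", .data$feature)) |>
    dplyr::filter(is.finite(.data$ccc))
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$bw), y = .data$ccc)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::geom_hline(yintercept = object$ccc_threshold, linetype = 2,
                        colour = "red") +
    ggplot2::facet_wrap(~family) +
    ggplot2::labs(x = "bin width", y = "test-retest CCC") +
    ggplot2::theme_minimal()
}

#' Plot the bin-width-pair reproducibility matrix
#'
#' @param report A `stability_report`.
#' @return A ggplot tile map of reproducible-feature counts per bin-width
#'   pair.
#' @export
plot_reproducibility_matrix <- function(report) {
  stopifnot(inherits(report, "stability_report"))
  ggplot2::ggplot(report$reproducibility,
                  ggplot2::aes(x = factor(.data$bw1), y = factor(.data$bw2),
                               fill = .data$n_reproducible)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n_reproducible),
                       colour = "white", size = 3) +
    ggplot2::labs(x = "bin width", y = "bin width", fill = "features") +
    ggplot2::theme_minimal()
}
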