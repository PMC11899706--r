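#' Run configuration for the full study pipeline
#'
#' Bundles every knob of the end-to-end run. The defaults reproduce the
#' study-mirroring configuration: the full synthetic cohorts, the 5..50
#' bin-width grid, CCC and Spearman cuts of 0.9, and classification at bin
#' width 25.
#'
#' @param cohort A [cohort_config()].
#' @param bin_widths Bin-width grid, default [bw_grid()].
#' @param ccc_threshold Repeatability/reproducibility CCC cut.
#' @param spearman_threshold Redundancy cut.
#' @param classify_bw Operating bin width for the classifiers.
#' @param classify_seed Seed for split, learner and bootstrap.
#' @param n_boot Bootstrap resamples for classifier CIs.
#' @param run_rfe Also train the RFE comparison model.
#' @return A `run_config` list.
#' @export
run_config <- function(cohort = cohort_config(), bin_widths = bw_grid(),
                       ccc_threshold = 0.9, spearman_threshold = 0.9,
                       classify_bw = 25, classify_seed = 7L, n_boot = 2000L,
                       run_rfe = TRUE) {
  structure(list(cohort = cohort, bin_widths = bin_widths,
                 ccc_threshold = ccc_threshold,
                 spearman_threshold = spearman_threshold,
                 classify_bw = classify_bw, classify_seed = classify_seed,
                 n_boot = n_boot, run_rfe = run_rfe),
            class = "run_config")
}

#' Run the complete study pipeline
#'
#' Executes all stages in order — synthetic cohort generation, feature
#' extraction at every bin width, the stability screen (repeatability,
#' redundancy removal, consistent core, cross-bin-width reproducibility) and
#' the classifier comparison (robust core features vs recursive feature
#' elimination vs label-randomized negative control) — and, when `out_dir`
#' is given, writes the manifest, the long feature tables, the per-bin-width
#' stability CSVs, the core-set file, the reproducibility-count matrix, the
#' per-model metric CSVs, ROC points and a markdown summary.
#'
#' @param config A [run_config()].
#' @param out_dir Optional output directory.
#' @param quiet Suppress per-stage progress messages.
#' @return A `pipeline_result`: list with `cohort`, `features_retest`,
#'   `features_class`, `stability`, `classifiers` (named list of
#'   `classifier_report`s), `config`.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  t0 <- Sys.time()
  stage <- function(what, expr) {
    s <- Sys.time()
    out <- tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", what, conditionMessage(e)))
    })
    say("[%s] done in %.1fs", what, as.numeric(Sys.time() - s, units = "secs"))
    out
  }

  cohort <- stage("synth", generate_study_cohorts(config$cohort))
  man <- cohort$manifest
  retest_ids <- man$scan_id[man$cohort == "retest"]
  class_ids <- man$scan_id[man$cohort == "classification"]

  features_retest <- stage("extract-retest",
    extract_features(cohort, config$bin_widths, scan_ids = retest_ids))
  features_class <- stage("extract-classification",
    extract_features(cohort, config$classify_bw, scan_ids = class_ids))

  stab <- stage("stability",
    stability_report(features_retest, man[man$cohort == "retest", ],
                     config$ccc_threshold, config$spearman_threshold))

  split <- make_split(man[man$cohort == "classification", ],
                      seed = config$classify_seed)
  # core features whose columns exist and are usable at the operating BW
  classifiers <- list()
  classifiers$robust <- stage("classify-robust",
    train_robust(features_class, split, stab$core, bw = config$classify_bw,
                 seed = config$classify_seed, n_boot = config$n_boot))
  if (config$run_rfe) {
    classifiers$rfe <- stage("classify-rfe",
      train_rfe(features_class, split, bw = config$classify_bw,
                seed = config$classify_seed, n_boot = config$n_boot))
  }
  classifiers$negative_control <- stage("classify-negative-control",
    negative_control(features_class, split, bw = config$classify_bw,
                     features_use = stab$core, seed = config$classify_seed,
                     n_boot = config$n_boot))

  result <- structure(list(cohort = cohort, features_retest = features_retest,
                           features_class = features_class, stability = stab,
                           split = split, classifiers = classifiers,
                           config = config),
                      class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  say("pipeline finished in %.1fs", as.numeric(Sys.time() - t0, units = "secs"))
  result
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  man <- result$cohort$manifest
  write.csv(man, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  write.csv(result$features_retest, file.path(out_dir, "features_retest.csv"),
            row.names = FALSE)
  write.csv(result$features_class, file.path(out_dir, "features_classification.csv"),
            row.names = FALSE)
  stab <- result$stability
  write.csv(stab$repeatability, file.path(out_dir, "stability_per_bw.csv"),
            row.names = FALSE)
  writeLines(stab$core, file.path(out_dir, "core_features.txt"))
  write.csv(stab$reproducibility, file.path(out_dir, "bw_pair_reproducibility.csv"),
            row.names = FALSE)
  for (tag in names(result$classifiers)) {
    rep <- result$classifiers[[tag]]
    write.csv(tidy(rep), file.path(out_dir, sprintf("classifier_%s_metrics.csv", tag)),
              row.names = FALSE)
    write.csv(roc_points(rep), file.path(out_dir, sprintf("classifier_%s_roc.csv", tag)),
              row.names = FALSE)
  }
  writeLines(pipeline_summary_md(result), file.path(out_dir, "summary.md"))
  invisible(out_dir)
}

pipeline_summary_md <- function(result) {
  stab <- result$stability
  fam_counts <- stab$repeatability |>
    dplyr::mutate(family = sub("_.*$", "", .data$feature)) |>
    dplyr::summarise(repeatable = sum(.data$repeatable),
                     .by = c("bw", "family")) |>
    tidyr::pivot_wider(names_from = "family", values_from = "repeatable")
  lines <- c("# Pipeline summary", "",
             sprintf("- scans: %d retest / %d classification",
                     sum(result$cohort$manifest$cohort == "retest"),
                     sum(result$cohort$manifest$cohort == "classification")),
             sprintf("- consistent core (%d features): %s",
                     length(stab$core), paste(stab$core, collapse = ", ")), "",
             "## Repeatable features per family per bin width", "",
             knit_md_table(fam_counts), "",
             "## Bin-width-pair reproducibility counts", "",
             knit_md_table(stab$reproducibility |>
                             tidyr::pivot_wider(names_from = "bw2",
                                                values_from = "n_reproducible")),
             "", "## Classifier test performance", "")
  for (tag in names(result$classifiers)) {
    g <- glance(result$classifiers[[tag]])
    lines <- c(lines, sprintf("- %s: macro AUC %.3f, accuracy %.3f (%d features)",
                              tag, g$test_macro_auc, g$test_accuracy, g$n_features))
  }
  lines
}

knit_md_table <- function(df) {
  df <- as.data.frame(df)
  fmt <- function(v) if (is.numeric(v)) formatC(v, format = "g", digits = 4) else as.character(v)
  cells <- vapply(df, fmt, character(nrow(df)))
  if (is.null(dim(cells))) cells <- matrix(cells, nrow = 1)
  body <- apply(cells, 1, paste, collapse = " | ")
  c(paste(names(df), collapse = " | "),
    paste(rep("---", ncol(df)), collapse = " | "),
    body)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  print(x$cohort)
  print(x$stability)
  for (r in x$classifiers) print(r)
  invisible(x)
}
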