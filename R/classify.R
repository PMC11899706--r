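#' Stratified train/test split with a cross-validation plan
#'
#' Deterministic stratified 70/30 split of the classification cohort plus a
#' stratified 5-fold cross-validation fold assignment on the training part,
#' so every model comparison runs on identical splits.
#'
#' @param manifest Tibble with columns `scan_id`, `class_label`.
#' @param seed Integer seed.
#' @param train_prop Training proportion, default 0.7.
#' @param n_folds Cross-validation folds, default 5.
#' @return Tibble with columns `scan_id`, `class_label`, `split`
#'   (`"train"`/`"test"`), `fold` (1..n_folds on train rows, NA on test).
#' @export
make_split <- function(manifest, seed = 1L, train_prop = 0.7, n_folds = 5L) {
  stopifnot(all(c("scan_id", "class_label") %in% names(manifest)))
  counts <- table(manifest$class_label)
  if (any(counts < 5L)) abort("every class needs at least 5 samples")
  set.seed(seed)
  out <- manifest |>
    dplyr::select("scan_id", "class_label") |>
    dplyr::group_by(.data$class_label) |>
    dplyr::group_modify(function(d, key) {
      n <- nrow(d)
      n_test <- round((1 - train_prop) * n)
      ord <- sample.int(n)
      d$split <- "train"
      d$split[ord[seq_len(n_test)]] <- "test"
      d
    }) |>
    dplyr::ungroup()
  train <- out[out$split == "train", ]
  if (any(table(train$class_label) < n_folds)) {
    abort("every class needs at least `n_folds` training samples")
  }
  folds <- train |>
    dplyr::group_by(.data$class_label) |>
    dplyr::group_modify(function(d, key) {
      d$fold <- (sample.int(nrow(d)) %% n_folds) + 1L
      d
    }) |>
    dplyr::ungroup()
  out |>
    dplyr::left_join(folds |> dplyr::select("scan_id", "fold"), by = "scan_id") |>
    dplyr::arrange(.data$scan_id)
}

# rank (Wilcoxon) AUC of scores for a binary indicator
auc_rank <- function(scores, positive) {
  np <- sum(positive); nn <- sum(!positive)
  if (np == 0L || nn == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[positive]) - np * (np + 1) / 2) / (np * nn)
}

#' One-vs-rest evaluation of multiclass scores
#'
#' Per-class one-vs-rest precision, recall and F1 at the argmax prediction,
#' per-class AUC (rank statistic of the class score against the rest),
#' overall accuracy and macro AUC, with stratified-bootstrap percentile
#' confidence intervals (resampling within each true class).
#'
#' @param scores Numeric matrix, rows = samples, named columns = classes.
#' @param truth Character/factor vector of true class labels.
#' @param n_boot Bootstrap resamples for the CIs, default 2000.
#' @param conf_level Confidence level, default 0.95.
#' @param seed Seed for the bootstrap.
#' @return Tibble with columns `class`, `metric`, `estimate`, `conf_low`,
#'   `conf_high`; overall rows carry class `"macro"`.
#' @export
evaluate_ovr <- function(scores, truth, n_boot = 2000L, conf_level = 0.95,
                         seed = 1L) {
  stopifnot(is.matrix(scores), !is.null(colnames(scores)),
            nrow(scores) == length(truth))
  truth <- as.character(truth)
  if (!all(truth %in% colnames(scores))) {
    abort("every true label must match a score column")
  }
  point <- ovr_metrics_once(scores, truth)
  set.seed(seed)
  idx_by_class <- split(seq_along(truth), truth)
  boot <- matrix(NA_real_, n_boot, nrow(point))
  for (b in seq_len(n_boot)) {
    idx <- unlist(lapply(idx_by_class, function(ix) {
      ix[sample.int(length(ix), replace = TRUE)]
    }), use.names = FALSE)
    boot[b, ] <- ovr_metrics_once(scores[idx, , drop = FALSE], truth[idx])$estimate
  }
  alpha <- (1 - conf_level) / 2
  point$conf_low <- apply(boot, 2, quantile, probs = alpha, na.rm = TRUE)
  point$conf_high <- apply(boot, 2, quantile, probs = 1 - alpha, na.rm = TRUE)
  point
}

ovr_metrics_once <- function(scores, truth) {
  classes <- colnames(scores)
  pred <- classes[max.col(scores, ties.method = "first")]
  rows <- lapply(classes, function(cl) {
    tp <- sum(pred == cl & truth == cl)
    fp <- sum(pred == cl & truth != cl)
    fn <- sum(pred != cl & truth == cl)
    precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    f1 <- if (isTRUE(precision + recall > 0)) {
      2 * precision * recall / (precision + recall)
    } else NA_real_
    auc <- auc_rank(scores[, cl], truth == cl)
    tibble(class = cl,
           metric = c("precision", "recall", "f1", "auc"),
           estimate = c(precision, recall, f1, auc))
  })
  macro_auc <- mean(vapply(classes, function(cl) auc_rank(scores[, cl], truth == cl),
                           numeric(1)), na.rm = TRUE)
  dplyr::bind_rows(c(rows, list(tibble(
    class = "macro", metric = c("accuracy", "auc"),
    estimate = c(mean(pred == truth), macro_auc)))))
}

# ---- gradient-boosted learner -----------------------------------------------

xgb_params <- function(n_classes, seed, eta = 0.1, max_depth = 3L) {
  list(objective = "multi:softprob", num_class = n_classes, eta = eta,
       max_depth = max_depth, subsample = 0.8, colsample_bytree = 0.8,
       nthread = 1L, seed = seed)
}

fit_xgb <- function(x, y_int, n_classes, nrounds, seed, dval = NULL,
                    early_stopping = 20L) {
  dtrain <- xgboost::xgb.DMatrix(as.matrix(x), label = y_int)
  if (is.null(dval)) {
    xgboost::xgb.train(params = xgb_params(n_classes, seed), data = dtrain,
                       nrounds = nrounds, verbose = 0)
  } else {
    xgboost::xgb.train(params = xgb_params(n_classes, seed), data = dtrain,
                       nrounds = nrounds, evals = list(val = dval),
                       early_stopping_rounds = early_stopping, verbose = 0)
  }
}

predict_scores <- function(model, x, classes) {
  p <- predict(model, xgboost::xgb.DMatrix(as.matrix(x)))
  p <- matrix(p, nrow = nrow(x), ncol = length(classes))
  colnames(p) <- classes
  p
}

# assemble the design matrix (scans x features) aligned with the split plan
design_matrix <- function(features, split, bw, feature_set = NULL) {
  wide <- features_wide(features, bw)
  wide <- wide[match(split$scan_id, wide$scan_id), , drop = FALSE]
  if (anyNA(wide$scan_id)) abort("split plan contains scan ids absent from the feature table")
  x <- as.data.frame(wide[, setdiff(names(wide), "scan_id"), drop = FALSE])
  if (!is.null(feature_set)) {
    missing <- setdiff(feature_set, names(x))
    if (length(missing)) abort(sprintf("features not in table: %s",
                                       paste(missing, collapse = ", ")))
    x <- x[, feature_set, drop = FALSE]
  }
  # drop non-finite columns (degenerate features) to keep the learner stable
  ok <- vapply(x, function(v) all(is.finite(v)), logical(1))
  x[, ok, drop = FALSE]
}

# core trainer shared by all three models
train_eval <- function(x, split, labels, seed, tag, nrounds_max = 300L,
                       n_boot = 2000L) {
  classes <- sort(unique(labels))
  if (length(classes) < 2L) abort("training requires at least 2 classes")
  y_int <- match(labels, classes) - 1L
  is_train <- split$split == "train"
  folds <- split$fold
  cv_rows <- list()
  best_iters <- integer()
  for (f in sort(unique(folds[is_train]))) {
    in_fit <- is_train & folds != f
    in_val <- is_train & folds == f
    dval <- xgboost::xgb.DMatrix(as.matrix(x[in_val, , drop = FALSE]),
                                 label = y_int[in_val])
    m <- fit_xgb(x[in_fit, , drop = FALSE], y_int[in_fit], length(classes),
                 nrounds_max, seed, dval = dval)
    bi <- xgboost::xgb.attr(m, "best_iteration")
    best_iters <- c(best_iters, if (is.null(bi)) nrounds_max else as.integer(bi))
    sc <- predict_scores(m, x[in_val, , drop = FALSE], classes)
    fold_truth <- labels[in_val]
    fold_auc <- mean(vapply(classes, function(cl) {
      auc_rank(sc[, cl], fold_truth == cl)
    }, numeric(1)), na.rm = TRUE)
    cv_rows[[length(cv_rows) + 1L]] <- tibble(fold = f, macro_auc = fold_auc)
  }
  cv <- dplyr::bind_rows(cv_rows)
  nrounds <- max(10L, round(mean(best_iters)))
  final <- fit_xgb(x[is_train, , drop = FALSE], y_int[is_train],
                   length(classes), nrounds, seed)
  is_test <- split$split == "test"
  sc_test <- predict_scores(final, x[is_test, , drop = FALSE], classes)
  truth_test <- split$class_label[is_test]
  metrics <- evaluate_ovr(sc_test, truth_test, n_boot = n_boot, seed = seed)
  tcrit <- stats::qt(0.975, df = max(1L, nrow(cv) - 1L))
  structure(list(
    model_tag = tag,
    features_used = colnames(x),
    nrounds = nrounds,
    cv = cv,
    cv_mean_auc = mean(cv$macro_auc),
    cv_ci = mean(cv$macro_auc) + c(-1, 1) * tcrit * sd(cv$macro_auc) / sqrt(nrow(cv)),
    test_metrics = metrics,
    test_scores = sc_test,
    test_truth = truth_test,
    accuracy = metrics$estimate[metrics$class == "macro" &
                                  metrics$metric == "accuracy"],
    macro_auc = metrics$estimate[metrics$class == "macro" &
                                   metrics$metric == "auc"],
    seed = seed),
    class = "classifier_report")
}

#' Train the robust-features classifier
#'
#' Gradient-boosted decision-tree ensemble (multiclass softprob) trained on
#' the consistent-core robust features only, with the number of boosting
#' rounds chosen by early stopping inside stratified cross-validation, then
#' refit on the full training split and evaluated one-vs-rest on the held-out
#' test split.
#'
#' @param features Long feature table from [extract_features()].
#' @param split Split plan from [make_split()].
#' @param core Character vector of robust feature names (non-empty).
#' @param bw Operating bin width, default 25.
#' @param seed Integer seed (learner and bootstrap).
#' @param n_boot Bootstrap resamples for metric CIs.
#' @return A `classifier_report`.
#' @export
train_robust <- function(features, split, core, bw = 25, seed = 1L,
                         n_boot = 2000L) {
  if (length(core) == 0L) abort("the robust feature set is empty")
  x <- design_matrix(features, split, bw, feature_set = core)
  train_eval(x, split, split$class_label, seed, "robust", n_boot = n_boot)
}

#' Train the recursive-feature-elimination classifier
#'
#' Backwards recursive feature elimination wrapped around the same
#' gradient-boosted learner: starting from all features, the model is fitted
#' on the training split and the feature with the lowest importance (gain)
#' is removed, one per step. The retained-set size is chosen by stratified
#' cross-validated macro AUC on the training split only; the winning subset
#' is then trained and evaluated exactly like the robust model. Test rows
#' are never touched during elimination or size selection.
#'
#' @inheritParams train_robust
#' @param rfe_nrounds Boosting rounds per elimination fit, default 60.
#' @param candidate_sizes Subset sizes evaluated by inner CV (default: a
#'   geometric ladder up to the feature count).
#' @return A `classifier_report`; `features_used` holds the selected subset.
#' @export
train_rfe <- function(features, split, bw = 25, seed = 1L, n_boot = 2000L,
                      rfe_nrounds = 60L, candidate_sizes = NULL) {
  x_all <- design_matrix(features, split, bw)
  labels <- split$class_label
  classes <- sort(unique(labels))
  y_int <- match(labels, classes) - 1L
  is_train <- split$split == "train"
  x_tr <- x_all[is_train, , drop = FALSE]
  y_tr <- y_int[is_train]

  # elimination path: drop the least important feature, one per step
  current <- colnames(x_all)
  path <- list()
  set.seed(seed)
  while (length(current) >= 1L) {
    path[[length(path) + 1L]] <- current
    if (length(current) == 1L) break
    m <- fit_xgb(x_tr[, current, drop = FALSE], y_tr, length(classes),
                 rfe_nrounds, seed)
    imp <- xgboost::xgb.importance(model = m)
    gain <- setNames(rep(0, length(current)), current)
    gain[imp$Feature] <- imp$Gain
    worst <- names(gain)[order(gain, names(gain))][1]
    current <- setdiff(current, worst)
  }
  sizes <- vapply(path, length, integer(1))
  candidate_sizes <- candidate_sizes %||%
    unique(pmin(max(sizes), c(1, 2, 3, 5, 8, 12, 18, 27, 40, 60, 88, 107)))
  candidate_sizes <- intersect(candidate_sizes, sizes)

  folds <- split$fold
  cv_auc_for <- function(feat) {
    aucs <- vapply(sort(unique(folds[is_train])), function(f) {
      in_fit <- is_train & folds != f
      in_val <- is_train & folds == f
      m <- fit_xgb(x_all[in_fit, feat, drop = FALSE], y_int[in_fit],
                   length(classes), rfe_nrounds, seed)
      sc <- predict_scores(m, x_all[in_val, feat, drop = FALSE], classes)
      truth <- labels[in_val]
      mean(vapply(classes, function(cl) auc_rank(sc[, cl], truth == cl),
                  numeric(1)), na.rm = TRUE)
    }, numeric(1))
    mean(aucs)
  }
  scores <- vapply(candidate_sizes,
                   function(s) cv_auc_for(path[[which(sizes == s)[1]]]),
                   numeric(1))
  best_size <- candidate_sizes[order(-scores, candidate_sizes)][1]
  selected <- path[[which(sizes == best_size)[1]]]

  rep <- train_eval(x_all[, selected, drop = FALSE], split, labels, seed,
                    "rfe", n_boot = n_boot)
  rep$rfe_path_sizes <- sizes
  rep$rfe_cv_scores <- setNames(scores, candidate_sizes)
  rep
}

#' Label-randomization negative control
#'
#' Permutes the training labels once (a single fixed permutation, unchanged
#' across cross-validation folds), trains the same learner as
#' [train_robust()], and evaluates against the true held-out test labels.
#' Chance-level test performance confirms that the real models' performance
#' does not stem from leakage or overfitting.
#'
#' @inheritParams train_robust
#' @param features_use Feature names to train on (default: all available).
#' @param perm_seed Seed of the single label permutation.
#' @return A `classifier_report` with tag `"negative_control"`; the applied
#'   permutation is stored as `$permutation`.
#' @export
negative_control <- function(features, split, bw = 25, features_use = NULL,
                             seed = 1L, perm_seed = seed + 1L, n_boot = 2000L) {
  x <- design_matrix(features, split, bw, feature_set = features_use)
  labels <- split$class_label
  is_train <- split$split == "train"
  set.seed(perm_seed)
  perm <- sample.int(sum(is_train))
  labels[is_train] <- labels[is_train][perm]
  # only the training labels are permuted; the test split keeps true labels,
  # so train_eval's held-out evaluation is already against the truth
  shuffled_split <- split
  shuffled_split$class_label <- labels
  rep <- train_eval(x, shuffled_split, labels, seed, "negative_control",
                    n_boot = n_boot)
  rep$permutation <- perm
  rep
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf("<classifier_report: %s> %d features, test macro AUC %.3f, accuracy %.3f\n",
              x$model_tag, length(x$features_used), x$macro_auc, x$accuracy))
  invisible(x)
}

#' @rdname train_robust
#' @param x A `classifier_report`.
#' @param ... Unused.
#' @export
tidy.classifier_report <- function(x, ...) {
  x$test_metrics |> dplyr::mutate(model = x$model_tag, .before = 1)
}

#' @rdname train_robust
#' @export
glance.classifier_report <- function(x, ...) {
  tibble(model = x$model_tag, n_features = length(x$features_used),
         nrounds = x$nrounds, cv_mean_auc = x$cv_mean_auc,
         test_macro_auc = x$macro_auc, test_accuracy = x$accuracy)
}

#' ROC curve points for a classifier report
#'
#' @param report A `classifier_report`.
#' @return Tibble with columns `class`, `fpr`, `tpr`.
#' @export
roc_points <- function(report) {
  stopifnot(inherits(report, "classifier_report"))
  classes <- colnames(report$test_scores)
  purrr::map_dfr(classes, function(cl) {
    pos <- report$test_truth == cl
    ord <- order(report$test_scores[, cl], decreasing = TRUE)
    tp <- cumsum(pos[ord]); fp <- cumsum(!pos[ord])
    tibble(class = cl,
           fpr = c(0, fp / max(1, sum(!pos))),
           tpr = c(0, tp / max(1, sum(pos))))
  })
}

#' @rdname roc_points
#' @param object A `classifier_report`.
#' @param ... Unused.
#' @export
autoplot.classifier_report <- function(object, ...) {
  ggplot2::ggplot(roc_points(object),
                  ggplot2::aes(x = .data$fpr, y = .data$tpr,
                               colour = .data$class)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::labs(title = sprintf("One-vs-rest ROC (%s)", object$model_tag),
                  x = "false positive rate", y = "true positive rate") +
    ggplot2::theme_minimal()
}
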