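# synthetic tabular cohort: two informative features separate the classes,
# the rest are pure noise
make_class_data <- function(n_per_class = c(bcc = 30, bowen = 20, nevus = 25),
                            n_noise = 10, seed = 41) {
  set.seed(seed)
  rows <- list()
  mu <- list(bcc = c(3, 0), bowen = c(0, 3), nevus = c(-3, -3))
  k <- 0
  for (cl in names(n_per_class)) {
    for (i in seq_len(n_per_class[[cl]])) {
      k <- k + 1
      vals <- c(rnorm(2, mu[[cl]], 1), rnorm(n_noise))
      rows[[k]] <- tibble::tibble(
        scan_id = sprintf("s%03d", k), class_label = cl,
        feature = c("inf_1", "inf_2", sprintf("noise_%02d", seq_len(n_noise))),
        value = vals)
    }
  }
  long <- dplyr::bind_rows(rows)
  long$bw <- 25
  manifest <- dplyr::distinct(long[, c("scan_id", "class_label")])
  list(features = long[, c("scan_id", "bw", "feature", "value")],
       manifest = manifest)
}

test_that("the stratified split reproduces per-class 70/30 arithmetic", {
  man <- tibble::tibble(scan_id = sprintf("s%03d", 1:134),
                        class_label = rep(c("bcc", "bowen", "nevus"),
                                          c(63, 31, 40)))
  sp <- make_split(man, seed = 5)
  test_counts <- table(sp$class_label[sp$split == "test"])
  expect_equal(as.integer(test_counts[c("bcc", "bowen", "nevus")]),
               as.integer(round(0.3 * c(63, 31, 40))))
  expect_equal(sum(sp$split == "train") + sum(sp$split == "test"), 134L)
  expect_length(intersect(sp$scan_id[sp$split == "train"],
                          sp$scan_id[sp$split == "test"]), 0L)
  # folds cover train only, stratified within a sample of proportionality
  expect_true(all(is.na(sp$fold[sp$split == "test"])))
  ftab <- table(sp$class_label[sp$split == "train"], sp$fold[sp$split == "train"])
  expect_true(all(abs(ftab - rowMeans(ftab)) <= 1))

  expect_identical(make_split(man, seed = 5), sp)
  expect_false(identical(make_split(man, seed = 6), sp))

  two <- man[man$class_label != "nevus", ]
  expect_equal(sort(unique(make_split(two, seed = 1)$class_label)),
               c("bcc", "bowen"))
  tiny <- man[c(1:4, 64:70, 95:110), ]
  expect_error(make_split(tiny, seed = 1), "at least 5")
})

test_that("one-vs-rest metrics are exact for perfect and hand-computed scores", {
  truth <- rep(c("a", "b", "c"), c(5, 4, 6))
  perfect <- t(vapply(truth, function(cl) {
    setNames(as.numeric(c("a", "b", "c") == cl), c("a", "b", "c"))
  }, numeric(3)))
  m <- evaluate_ovr(perfect, truth, n_boot = 50, seed = 1)
  expect_true(all(m$estimate[m$metric == "auc"] == 1))
  expect_equal(m$estimate[m$class == "macro" & m$metric == "accuracy"], 1)

  # toy confusion: one "a" sample predicted as "b", everything else correct
  scores <- perfect
  scores[1, ] <- c(0.2, 0.7, 0.1)
  m2 <- evaluate_ovr(scores, truth, n_boot = 50, seed = 1)
  g <- function(cl, met) m2$estimate[m2$class == cl & m2$metric == met]
  expect_equal(g("a", "precision"), 1)        # 4 TP, 0 FP
  expect_equal(g("a", "recall"), 4 / 5)       # 1 FN
  expect_equal(g("b", "precision"), 4 / 5)    # 4 TP, 1 FP
  expect_equal(g("b", "recall"), 1)
  expect_equal(g("a", "f1"), 2 * (1 * 0.8) / 1.8)
  expect_equal(g("macro", "accuracy"), 14 / 15)
})

test_that("label-independent scores give chance-level AUC with honest CIs", {
  set.seed(42)
  n <- 600
  truth <- sample(c("a", "b", "c"), n, replace = TRUE)
  scores <- matrix(runif(3 * n), n, 3, dimnames = list(NULL, c("a", "b", "c")))
  m <- evaluate_ovr(scores, truth, n_boot = 200, seed = 2)
  aucs <- m$estimate[m$metric == "auc"]
  expect_true(all(abs(aucs - 0.5) < 0.08))
  expect_true(all(m$conf_low <= m$estimate + 1e-12 &
                    m$estimate <= m$conf_high + 1e-12))
})

test_that("the rank AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(43)
  for (rep in 1:10) {
    y <- sample(c(TRUE, FALSE), 40, replace = TRUE, prob = c(0.4, 0.6))
    if (length(unique(y)) < 2) next
    s <- rnorm(40) + y
    ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                          direction = "<", levels = c(FALSE, TRUE))))
    expect_equal(octradiomics:::auc_rank(s, y), ref, tolerance = 1e-12)
  }
})

test_that("the robust model separates well-separated synthetic classes", {
  d <- make_class_data()
  sp <- make_split(d$manifest, seed = 3)
  rep <- train_robust(d$features, sp, core = c("inf_1", "inf_2"),
                      seed = 3, n_boot = 100)
  expect_gte(rep$macro_auc, 0.9)
  rep2 <- train_robust(d$features, sp, core = c("inf_1", "inf_2"),
                       seed = 3, n_boot = 100)
  expect_equal(glance(rep), glance(rep2))
  expect_equal(rep$test_metrics$estimate, rep2$test_metrics$estimate)
  expect_error(train_robust(d$features, sp, core = character()), "empty")

  one_class <- sp
  one_class$class_label <- "bcc"
  expect_error(octradiomics:::train_eval(
    data.frame(x = rnorm(nrow(sp))), one_class, one_class$class_label, 1, "t"),
    "2 classes")
})

test_that("RFE prefers informative features and never sees test rows", {
  d <- make_class_data(n_noise = 12, seed = 44)
  sp <- make_split(d$manifest, seed = 4)
  rep <- train_rfe(d$features, sp, seed = 4, n_boot = 50,
                   candidate_sizes = c(1, 2, 4, 8, 14))
  expect_lte(length(rep$features_used), 14)
  expect_true(all(c("inf_1", "inf_2") %in% rep$features_used) ||
                length(rep$features_used) < 2)
  # noise features should be mostly eliminated
  expect_lte(sum(grepl("noise", rep$features_used)),
             length(rep$features_used) - 1)

  # leakage isolation: scrambling the *test-row* feature values leaves the
  # selected subset unchanged
  d2 <- d
  test_ids <- sp$scan_id[sp$split == "test"]
  scramble <- d2$features$scan_id %in% test_ids
  set.seed(99)
  d2$features$value[scramble] <- sample(d2$features$value[scramble])
  rep2 <- train_rfe(d2$features, sp, seed = 4, n_boot = 50,
                    candidate_sizes = c(1, 2, 4, 8, 14))
  expect_identical(sort(rep$features_used), sort(rep2$features_used))
})

test_that("the negative control sits at chance and fixes one permutation", {
  d <- make_class_data(n_per_class = c(bcc = 40, bowen = 30, nevus = 35),
                       seed = 45)
  sp <- make_split(d$manifest, seed = 5)
  nc <- negative_control(d$features, sp, features_use = c("inf_1", "inf_2"),
                         seed = 5, n_boot = 50)
  # chance level, with slack for the anti-informative drift a permuted-label
  # model shows on genuinely informative features at this test-set size
  expect_gte(nc$macro_auc, 0.15)
  expect_lte(nc$macro_auc, 0.85)
  # the permutation is drawn once, before training, and stored
  expect_length(nc$permutation, sum(sp$split == "train"))
  nc_again <- negative_control(d$features, sp, features_use = c("inf_1", "inf_2"),
                               seed = 5, n_boot = 50)
  expect_identical(nc$permutation, nc_again$permutation)
  nc2 <- negative_control(d$features, sp, features_use = c("inf_1", "inf_2"),
                          seed = 5, perm_seed = 77, n_boot = 50)
  expect_false(identical(nc$permutation, nc2$permutation))
  expect_gte(nc2$macro_auc, 0.15)
  expect_lte(nc2$macro_auc, 0.85)
})

test_that("report accessors expose tidy metrics and ROC points", {
  d <- make_class_data(seed = 46)
  sp <- make_split(d$manifest, seed = 6)
  rep <- train_robust(d$features, sp, core = c("inf_1", "inf_2"), seed = 6,
                      n_boot = 50)
  td <- tidy(rep)
  expect_true(all(c("model", "class", "metric", "estimate") %in% names(td)))
  expect_true(all(td$estimate >= 0 & td$estimate <= 1, na.rm = TRUE))
  roc <- roc_points(rep)
  expect_true(all(roc$fpr >= 0 & roc$fpr <= 1))
  expect_true(all(diff(roc$fpr[roc$class == roc$class[1]]) >= 0))
  expect_s3_class(autoplot(rep), "ggplot")
})
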