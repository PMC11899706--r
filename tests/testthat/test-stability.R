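test_that("CCC reproduces the worked values and basic identities", {
  expect_equal(ccc(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(ccc(c(1, 2, 3), c(2, 3, 4)), 4 / 7)
  expect_equal(ccc(c(1, 2, 3), c(3, 2, 1)), -1)
  expect_true(is.na(ccc(rep(2, 5), rep(7, 5))))
  expect_error(ccc(1:4, 1:3), "equal length")
  expect_error(ccc(1:2, 1:2), "at least 3")
})

test_that("CCC matches brute-force moment computation, is symmetric and attenuated", {
  set.seed(31)
  for (rep in 1:200) {
    n <- sample(3:40, 1)
    x <- rnorm(n, sd = runif(1, 0.5, 5))
    y <- 0.5 * x + rnorm(n, mean = runif(1, -2, 2))
    expect_equal(ccc(x, y), bf_ccc(x, y), tolerance = 1e-12)
    expect_equal(ccc(x, y), ccc(y, x))
    expect_lte(abs(ccc(x, y)), abs(cor(x, y)) + 1e-12)
    expect_equal(ccc(x, x), 1)
  }
})

make_paired_features <- function(n_lesions = 10, seed = 32) {
  # synthetic paired tables: f_good repeats, f_noise does not, f_const is flat
  set.seed(seed)
  base <- rnorm(n_lesions, 50, 10)
  man <- tibble::tibble(
    scan_id = c(sprintf("L%02d_T1", 1:n_lesions), sprintf("L%02d_T2", 1:n_lesions)),
    lesion_id = rep(sprintf("L%02d", 1:n_lesions), 2),
    timepoint = rep(1:2, each = n_lesions))
  long <- dplyr::bind_rows(
    tibble::tibble(scan_id = man$scan_id, bw = 25,
                   feature = "f_good",
                   value = c(base, base + rnorm(n_lesions, 0, 0.5))),
    tibble::tibble(scan_id = man$scan_id, bw = 25,
                   feature = "f_noise", value = rnorm(2 * n_lesions)),
    tibble::tibble(scan_id = man$scan_id, bw = 25,
                   feature = "f_const", value = 1))
  list(features = long, manifest = man)
}

test_that("repeatability screen keeps agreeing features and drops noise", {
  d <- make_paired_features()
  scr <- repeatability_screen(d$features, d$manifest, bw = 25)
  scr <- tibble::deframe(scr[, c("feature", "repeatable")])
  expect_true(scr[["f_good"]])
  expect_false(scr[["f_noise"]])
  expect_false(scr[["f_const"]])  # undefined CCC is non-evaluable
})

test_that("identical retest makes every non-constant feature repeatable", {
  d <- make_paired_features()
  feats <- d$features
  # overwrite retest values with the test values
  t1 <- feats$value[grepl("T1", feats$scan_id)]
  feats$value[grepl("T2", feats$scan_id)] <- t1
  scr <- repeatability_screen(feats, d$manifest, bw = 25)
  expect_true(all(scr$repeatable[scr$feature != "f_const"]))
})

test_that("the repeatability cut is inclusive at the threshold", {
  d <- make_paired_features()
  scr <- repeatability_screen(d$features, d$manifest, bw = 25)
  c_good <- scr$ccc[scr$feature == "f_good"]
  at_cut <- repeatability_screen(d$features, d$manifest, bw = 25,
                                 threshold = c_good)
  expect_true(at_cut$repeatable[at_cut$feature == "f_good"])
})

test_that("raising the CCC threshold never enlarges the repeatable set", {
  d <- make_paired_features(n_lesions = 15, seed = 33)
  sets <- lapply(c(0.5, 0.7, 0.9, 0.99), function(th) {
    scr <- repeatability_screen(d$features, d$manifest, bw = 25, threshold = th)
    scr$feature[scr$repeatable]
  })
  for (k in 2:length(sets)) expect_true(all(sets[[k]] %in% sets[[k - 1]]))
})

test_that("Spearman dedup removes exact duplicates keeping the higher CCC", {
  set.seed(34)
  f <- rnorm(20, 10, 3)
  values <- tibble::tibble(scan_id = sprintf("s%02d", 1:20),
                           f_a = f, f_b = 2 * f, f_c = rnorm(20))
  kept <- spearman_dedup(c("f_a", "f_b", "f_c"), values,
                         c(f_a = 0.95, f_b = 0.92, f_c = 0.91))
  expect_setequal(kept, c("f_a", "f_c"))

  # all pairwise correlations below the cut: nothing is removed
  set.seed(35)
  v2 <- tibble::tibble(scan_id = sprintf("s%02d", 1:30),
                       g1 = rnorm(30), g2 = rnorm(30), g3 = rnorm(30))
  expect_setequal(spearman_dedup(c("g1", "g2", "g3"), v2,
                                 c(g1 = 0.9, g2 = 0.9, g3 = 0.9)),
                  c("g1", "g2", "g3"))
})

test_that("among three mutually correlated features only the best CCC survives", {
  set.seed(36)
  f <- sort(rnorm(25))
  values <- tibble::tibble(scan_id = sprintf("s%02d", 1:25),
                           h1 = f, h2 = f + 0.001 * seq_along(f),
                           h3 = 3 * f - 1)
  kept <- spearman_dedup(c("h1", "h2", "h3"), values,
                         c(h1 = 0.95, h2 = 0.92, h3 = 0.99))
  expect_equal(kept, "h3")
})

test_that("the consistent core is the intersection of per-bin-width sets", {
  sets <- list(`5` = c("a", "b", "c"), `10` = c("a", "b", "c"),
               `15` = c("a", "b", "c"))
  expect_setequal(consistent_core(sets)$core, c("a", "b", "c"))
  sets$`10` <- c("a", "c")
  out <- consistent_core(sets)
  expect_setequal(out$core, c("a", "c"))
  expect_false("b" %in% out$core)
})

test_that("cross-bin-width reproducibility is symmetric with a full diagonal", {
  scan_ids <- sprintf("s%02d", 1:8)
  set.seed(37)
  base <- rnorm(8, 100, 20)
  long <- purrr::map_dfr(c(5, 10, 25), function(b) {
    dplyr::bind_rows(
      tibble::tibble(scan_id = scan_ids, bw = b, feature = "stable",
                     value = base + rnorm(8, 0, 0.1)),
      tibble::tibble(scan_id = scan_ids, bw = b, feature = "shifty",
                     value = base * b),
      tibble::tibble(scan_id = scan_ids, bw = b, feature = "shape_like",
                     value = base))
  })
  rep <- cross_bw_reproducibility(long)
  m <- tidyr::pivot_wider(rep, names_from = "bw2", values_from = "n_reproducible")
  # symmetry
  expect_equal(rep$n_reproducible,
               rep[match(paste(rep$bw2, rep$bw1), paste(rep$bw1, rep$bw2)), ]$n_reproducible)
  diag_counts <- rep$n_reproducible[rep$bw1 == rep$bw2]
  expect_true(all(diag_counts == 3))
  # the bin-width-proportional feature never agrees across widths
  off <- rep$n_reproducible[rep$bw1 != rep$bw2]
  expect_true(all(off <= 2))
  # the bin-width-invariant feature always does
  expect_true(all(off >= 1))
})
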