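qroi_from_levels <- function(lev, ng = max(lev)) {
  structure(list(levels = array(as.integer(lev), dim = dim(lev)), ng = as.integer(ng),
                 bin_width = 1, anchor = 0, n_voxels = sum(lev > 0),
                 spacing = c(1, 1, 1)),
            class = "quantized_roi")
}

test_that("two-voxel GLCM matches exhaustive pair enumeration", {
  q <- qroi_from_levels(array(c(1L, 2L), c(2, 1, 1)))
  counts <- octradiomics:::.cpp_glcm_counts(q$levels, q$ng)
  # direction 1 is the x axis: one pair, symmetric
  p <- counts[, , 1] / sum(counts[, , 1])
  expect_equal(p[1, 2], 0.5)
  expect_equal(p[2, 1], 0.5)
  fv <- glcm_features(q)
  expect_equal(unname(fv["glcm_MaximumProbability"]), 0.5)
})

test_that("normalized GLCM sums to one in every direction with pairs", {
  set.seed(21)
  q <- random_tiny_qroi()
  counts <- octradiomics:::.cpp_glcm_counts(q$levels, q$ng)
  for (d in seq_len(dim(counts)[3])) {
    tot <- sum(counts[, , d])
    if (tot > 0) expect_equal(sum(counts[, , d] / tot), 1)
    # symmetry per direction
    expect_equal(counts[, , d], t(counts[, , d]))
  }
})

test_that("an in-plane checkerboard has GLCM correlation -1 along both axes", {
  n <- 6L
  base <- outer(1:n, 1:n, function(a, b) ((a + b) %% 2L) + 1L)
  q <- qroi_from_levels(array(base, c(n, n, 1)), ng = 2L)
  counts <- octradiomics:::.cpp_glcm_counts(q$levels, q$ng)
  for (d in 1:2) {  # x and y axes: neighbours always alternate
    f <- octradiomics:::glcm_features_one(counts[, , d], 2L)
    expect_equal(unname(f["Correlation"]), -1)
  }
})

test_that("degenerate single-level ROI takes the documented GLCM conventions", {
  q <- qroi_from_levels(array(1L, c(3, 3, 1)), ng = 1L)
  fv <- glcm_features(q)
  expect_equal(unname(fv["glcm_Correlation"]), 1)
  expect_equal(unname(fv["glcm_MCC"]), 1)
  expect_equal(unname(fv["glcm_Contrast"]), 0)
})

test_that("1D run example gives long-run emphasis 2.5 along its axis", {
  q <- qroi_from_levels(array(c(1L, 1L, 2L), c(3, 1, 1)))
  counts <- octradiomics:::.cpp_glrlm_counts(q$levels, q$ng)
  # direction 1 = x: runs {level 1 len 2, level 2 len 1}
  m <- counts[, , 1]
  expect_equal(m[1, 2], 1)
  expect_equal(m[2, 1], 1)
  lre <- sum(m %*% diag(seq_len(ncol(m))^2)) / sum(m)
  expect_equal(lre, (4 + 1) / 2)
})

test_that("run lengths conserve the voxel count in every direction", {
  set.seed(22)
  for (rep in 1:5) {
    q <- random_tiny_qroi()
    counts <- octradiomics:::.cpp_glrlm_counts(q$levels, q$ng)
    jw <- seq_len(dim(counts)[2])
    for (d in seq_len(dim(counts)[3])) {
      expect_equal(sum(counts[, , d] %*% jw), q$n_voxels)
    }
  }
})

test_that("a constant line is a single run with quadratic long-run emphasis", {
  L <- 7L
  q <- qroi_from_levels(array(1L, c(L, 1, 1)), ng = 1L)
  counts <- octradiomics:::.cpp_glrlm_counts(q$levels, q$ng)
  m <- matrix(counts[, , 1], nrow = 1)
  expect_equal(sum(m), 1)
  expect_equal(m[1, L], 1)
  lre <- sum(m %*% diag(seq_len(ncol(m))^2)) / sum(m)
  expect_equal(lre, L^2)
})

test_that("size zones match the worked 2x2 example and partition the ROI", {
  lev <- array(c(1L, 1L, 1L, 2L), c(2, 2, 1))
  q <- qroi_from_levels(lev)
  zones <- octradiomics:::.cpp_glszm_zones(q$levels, q$ng)
  expect_equal(nrow(zones), 2L)
  expect_setequal(zones[, "size"], c(3L, 1L))
  fv <- glszm_features(q)
  # (1/1^2 * 1 + 1/2^2 * 1) / 2 zones
  expect_equal(unname(fv["glszm_LowGrayLevelZoneEmphasis"]), 0.625)

  set.seed(23)
  q2 <- random_tiny_qroi()
  z2 <- octradiomics:::.cpp_glszm_zones(q2$levels, q2$ng)
  expect_equal(sum(z2[, "size"]), q2$n_voxels)
  # constant ROI collapses to one zone
  q3 <- qroi_from_levels(array(1L, c(3, 2, 2)), ng = 1L)
  expect_equal(nrow(octradiomics:::.cpp_glszm_zones(q3$levels, 1L)), 1L)
})

test_that("dependence counts match the worked examples and conserve voxels", {
  q <- qroi_from_levels(array(1L, c(2, 2, 1)), ng = 1L)
  m <- octradiomics:::.cpp_gldm_counts(q$levels, q$ng)
  expect_equal(m[1, 4], 4)   # every voxel has 3 dependent neighbours
  expect_equal(sum(m), 4)

  # no two neighbours share a level -> all dependence sizes are 1
  lev <- array(c(1L, 2L, 3L, 4L), c(2, 2, 1))
  q2 <- qroi_from_levels(lev)
  m2 <- octradiomics:::.cpp_gldm_counts(q2$levels, q2$ng)
  expect_equal(sum(m2[, 1]), 4)
  expect_equal(sum(m2[, -1]), 0)

  set.seed(24)
  q3 <- random_tiny_qroi()
  expect_equal(sum(octradiomics:::.cpp_gldm_counts(q3$levels, q3$ng)),
               q3$n_voxels)
})

test_that("gray-tone difference table matches a brute-force neighbour-mean oracle", {
  q <- qroi_from_levels(array(c(1L, 1L, 1L, 2L), c(2, 2, 1)))
  tab <- octradiomics:::.cpp_ngtdm_counts(q$levels, q$ng)
  oracle <- bf_ngtdm(q$levels, q$ng)
  expect_equal(tab[, 1], oracle[, 1], ignore_attr = TRUE)
  expect_equal(tab[, 2], oracle[, 2], ignore_attr = TRUE)

  # constant ROI: all differences vanish, contrast 0, coarseness capped
  qc <- qroi_from_levels(array(1L, c(3, 3, 1)), ng = 1L)
  fv <- ngtdm_features(qc)
  expect_equal(unname(fv["ngtdm_Contrast"]), 0)
  expect_equal(unname(fv["ngtdm_Coarseness"]), 1e6)
})

test_that("all five matrix builders match brute-force enumeration on random ROIs", {
  set.seed(25)
  for (rep in 1:30) {
    q <- random_tiny_qroi()
    expect_equal(octradiomics:::.cpp_glcm_counts(q$levels, q$ng),
                 bf_glcm(q$levels, q$ng), ignore_attr = TRUE)
    expect_equal(octradiomics:::.cpp_glrlm_counts(q$levels, q$ng),
                 bf_glrlm(q$levels, q$ng), ignore_attr = TRUE)
    zones <- octradiomics:::.cpp_glszm_zones(q$levels, q$ng)
    bf_z <- bf_glszm(q$levels, q$ng)
    expect_equal(sort_zone_table(zones), sort_zone_table(bf_z))
    expect_equal(octradiomics:::.cpp_gldm_counts(q$levels, q$ng),
                 bf_gldm(q$levels, q$ng), ignore_attr = TRUE)
    expect_equal(octradiomics:::.cpp_ngtdm_counts(q$levels, q$ng),
                 bf_ngtdm(q$levels, q$ng), ignore_attr = TRUE)
  }
})
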