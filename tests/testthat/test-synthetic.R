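test_that("lesion rendering is deterministic under a fixed seed", {
  a <- small_scan(seed = 5)
  b <- small_scan(seed = 5)
  expect_identical(a$volume$values, b$volume$values)
  expect_identical(a$mask$values, b$mask$values)
  c <- small_scan(seed = 6)
  expect_false(identical(a$volume$values, c$volume$values))
})

test_that("zero texture contrast and noise give a flat lesion interior", {
  params <- lesion_class_params("nevus", texture_contrast = 0, intensity_sd = 0,
                                ellipsoid_semi_axes = c(0.4, 0.35, 0.25))
  scan <- generate_lesion_volume(params, shape = c(36L, 36L, 24L),
                                 spacing = c(0.05, 0.05, 0.05), seed = 2)
  inside <- scan$volume$values[scan$mask$values == 1L]
  expect_true(all(inside == params$mean_intensity))
})

test_that("mask voxel count matches the analytic ellipsoid volume within 5%", {
  params <- lesion_class_params("nevus", ellipsoid_semi_axes = c(1.5, 1.0, 0.5))
  scan <- generate_lesion_volume(params, shape = c(80L, 56L, 40L),
                                 spacing = c(0.05, 0.05, 0.05), seed = 3)
  analytic <- 4 / 3 * pi * 1.5 * 1.0 * 0.5 / 0.05^3
  expect_lt(abs(sum(scan$mask$values) - analytic) / analytic, 0.05)
})

test_that("a lesion exceeding the volume bounds is rejected explicitly", {
  params <- lesion_class_params("bcc")  # 1.4 mm semi-axis
  expect_error(generate_lesion_volume(params, shape = c(30L, 30L, 20L),
                                      spacing = c(0.05, 0.05, 0.05), seed = 1),
               "exceeds volume bounds")
})

test_that("zero perturbation makes the retest voxel-identical to the test", {
  params <- lesion_class_params("nevus", ellipsoid_semi_axes = c(0.45, 0.35, 0.25))
  pair <- generate_retest_pair(params, retest_perturbation(0, 0, 0),
                               shape = c(40L, 36L, 28L),
                               spacing = c(0.05, 0.05, 0.05), seed = 9)
  expect_identical(pair$test$volume$values, pair$retest$volume$values)
  expect_identical(pair$test$mask$values, pair$retest$mask$values)
})

test_that("a large translation visibly displaces the retest mask centroid", {
  params <- lesion_class_params("nevus", ellipsoid_semi_axes = c(0.4, 0.35, 0.25))
  pair <- generate_retest_pair(params,
                               retest_perturbation(translation_sd = 0.2,
                                                   axial_scale_sd = 0,
                                                   speckle_sd = 0),
                               shape = c(48L, 44L, 32L),
                               spacing = c(0.05, 0.05, 0.05), seed = 4)
  centroid <- function(m) colMeans(which(m$values == 1L, arr.ind = TRUE))
  disp <- sqrt(sum((centroid(pair$test$mask) - centroid(pair$retest$mask))^2))
  expect_gt(disp, 0)
  expect_equal(disp * 0.05, sqrt(sum(pair$shift^2)), tolerance = 0.15)
})

test_that("perturbation SDs must be non-negative", {
  expect_error(retest_perturbation(translation_sd = -0.1), ">= 0")
})

test_that("default study composition yields 80 retest and 134 classification scans", {
  coh <- generate_study_cohorts(cohort_config())
  man <- coh$manifest
  expect_equal(sum(man$cohort == "retest"), 80L)
  expect_equal(sum(man$cohort == "classification"), 134L)
  cls <- table(man$class_label[man$cohort == "classification"])
  expect_equal(as.integer(cls[c("bcc", "bowen", "nevus")]), c(63L, 31L, 40L))
  # every lesion in the retest arm appears at both timepoints
  tp <- table(man$lesion_id[man$cohort == "retest"])
  expect_true(all(tp == 2L))
})

test_that("a minimal one-subject one-lesion cohort has a two-row retest manifest", {
  cfg <- cohort_config(n_subjects = 1L, lesions_per_subject = 1L,
                       class_counts = c(bcc = 0L, bowen = 0L, nevus = 0L))
  man <- generate_study_cohorts(cfg)$manifest
  expect_equal(nrow(man), 2L)
  expect_equal(man$timepoint, c(1L, 2L))
})

test_that("invalid cohort configurations are rejected", {
  expect_error(cohort_config(class_counts = c(bcc = -1L, bowen = 1L, nevus = 1L)),
               "non-negative")
  expect_error(cohort_config(class_counts = c(unknown = 3L)), "class_params")
})

test_that("class mean intensities separate more than the within-class spread", {
  man <- generate_study_cohorts(small_cohort_config())$manifest
  man <- man[man$cohort == "classification", ]
  stats <- tapply(man$gt_mean_intensity, man$class_label, function(v) {
    c(mean = mean(v), sd = sd(v))
  })
  cls <- names(stats)
  for (a in cls) for (b in setdiff(cls, a)) {
    gap <- abs(stats[[a]]["mean"] - stats[[b]]["mean"])
    expect_gt(gap, stats[[a]]["sd"])
  }
})

test_that("cohorts can be written to NRRD files plus manifest and read back", {
  cfg <- small_cohort_config(n_subjects = 1L, lesions_per_subject = 1L,
                             class_counts = c(bcc = 0L, bowen = 0L, nevus = 1L))
  coh <- generate_study_cohorts(cfg)
  dir <- withr::local_tempdir()
  man <- write_cohort(coh, dir)
  expect_true(all(file.exists(man$volume_path)))
  expect_true(all(file.exists(man$mask_path)))
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  back <- read_nrrd(man$volume_path[1])
  orig <- render_scan(coh, man$scan_id[1])
  expect_equal(back$values, orig$volume$values)
  expect_equal(read_mask(man$mask_path[1])$values, orig$mask$values)
})
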