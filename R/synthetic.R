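#' Lesion class parameters for the synthetic OCT generator
#'
#' Describes one lesion class of the synthetic cohort: an axis-aligned
#' ellipsoidal lesion whose interior is a correlated Gaussian texture field
#' plus white noise, embedded in a depth-attenuated layered background.
#' Defaults give three well-separated classes (nevus-like, BCC-like,
#' Bowen-like) differing in texture scale, contrast, mean intensity and size.
#'
#' @param class_label One of `"nevus"`, `"bcc"`, `"bowen"`.
#' @param texture_correlation_length Spatial scale of the correlated random
#'   field, mm.
#' @param texture_contrast Amplitude (gray values) multiplying the unit-
#'   variance texture field.
#' @param mean_intensity Mean lesion gray value in \[0, 255\].
#' @param intensity_sd Within-lesion white-noise SD, gray values.
#' @param ellipsoid_semi_axes Semi-axes (a, b, c) in mm, a >= b >= c > 0.
#' @return A `lesion_class_params` list.
#' @export
lesion_class_params <- function(class_label = c("nevus", "bcc", "bowen"),
                                texture_correlation_length = NULL,
                                texture_contrast = NULL,
                                mean_intensity = NULL,
                                intensity_sd = NULL,
                                ellipsoid_semi_axes = NULL) {
  class_label <- match.arg(class_label)
  def <- switch(class_label,
    nevus = list(texture_correlation_length = 0.20, texture_contrast = 20,
                 mean_intensity = 100, intensity_sd = 8,
                 ellipsoid_semi_axes = c(1.2, 0.9, 0.5)),
    bcc   = list(texture_correlation_length = 0.10, texture_contrast = 35,
                 mean_intensity = 150, intensity_sd = 12,
                 ellipsoid_semi_axes = c(1.4, 1.0, 0.6)),
    bowen = list(texture_correlation_length = 0.30, texture_contrast = 30,
                 mean_intensity = 70, intensity_sd = 10,
                 ellipsoid_semi_axes = c(1.0, 0.8, 0.4)))
  p <- list(class_label = class_label,
            texture_correlation_length =
              texture_correlation_length %||% def$texture_correlation_length,
            texture_contrast = texture_contrast %||% def$texture_contrast,
            mean_intensity = mean_intensity %||% def$mean_intensity,
            intensity_sd = intensity_sd %||% def$intensity_sd,
            ellipsoid_semi_axes = ellipsoid_semi_axes %||% def$ellipsoid_semi_axes)
  ax <- p$ellipsoid_semi_axes
  if (length(ax) != 3L || any(!is.finite(ax)) || any(ax <= 0) || is.unsorted(rev(ax))) {
    abort("`ellipsoid_semi_axes` must be 3 positive numbers with a >= b >= c")
  }
  if (p$mean_intensity < 0 || p$mean_intensity > 255) {
    abort("`mean_intensity` must lie in [0, 255]")
  }
  if (p$intensity_sd < 0 || p$texture_contrast < 0 || p$texture_correlation_length <= 0) {
    abort("noise SDs must be >= 0 and the correlation length positive")
  }
  structure(p, class = "lesion_class_params")
}

#' Test-retest perturbation model
#'
#' The retest scan of a lesion re-renders the same underlying texture field
#' after a small rigid translation and an axial compression (emulating probe
#' pressure), and receives fresh multiplicative speckle. All SDs zero makes
#' the retest voxel-identical to the test.
#'
#' @param translation_sd SD of the per-axis rigid translation, mm.
#' @param axial_scale_sd SD of the axial (depth) scale factor around 1.
#' @param speckle_sd Gray-value scale of the independent multiplicative
#'   log-normal speckle applied to each scan.
#' @return A `retest_perturbation` list.
#' @export
retest_perturbation <- function(translation_sd = 0.1, axial_scale_sd = 0.05,
                                speckle_sd = 8) {
  if (any(c(translation_sd, axial_scale_sd, speckle_sd) < 0)) {
    abort("perturbation SDs must be >= 0")
  }
  structure(list(translation_sd = translation_sd, axial_scale_sd = axial_scale_sd,
                 speckle_sd = speckle_sd),
            class = "retest_perturbation")
}

#' Synthetic study configuration
#'
#' Defaults mirror the study design: a test-retest arm of 20 subjects with 2
#' nevi each, every nevus scanned twice (80 scans), and a three-class
#' classification arm of 63 BCC + 31 Bowen + 40 nevus scans (134 scans).
#'
#' @param n_subjects Subjects in the test-retest arm.
#' @param lesions_per_subject Nevi per subject.
#' @param class_counts Named counts for the classification arm.
#' @param volume_shape Voxels per axis (x, y, z).
#' @param voxel_spacing mm per voxel.
#' @param class_params Named list of [lesion_class_params()] per class.
#' @param perturbation A [retest_perturbation()].
#' @param master_seed Integer master seed; every output is a pure function of
#'   the configuration and this seed.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_subjects = 20L, lesions_per_subject = 2L,
                          class_counts = c(bcc = 63L, bowen = 31L, nevus = 40L),
                          volume_shape = c(128L, 128L, 64L),
                          voxel_spacing = c(0.05, 0.05, 0.05),
                          class_params = NULL,
                          perturbation = retest_perturbation(),
                          master_seed = 20250101L) {
  class_params <- class_params %||% list(
    nevus = lesion_class_params("nevus"),
    bcc = lesion_class_params("bcc"),
    bowen = lesion_class_params("bowen"))
  if (is.null(names(class_counts)) || !all(names(class_counts) %in% names(class_params))) {
    abort("`class_counts` must be named with classes present in `class_params`")
  }
  if (any(class_counts < 0) || any(class_counts != round(class_counts))) {
    abort("`class_counts` must be non-negative integers")
  }
  structure(list(n_subjects = as.integer(n_subjects),
                 lesions_per_subject = as.integer(lesions_per_subject),
                 class_counts = class_counts,
                 volume_shape = as.integer(volume_shape),
                 voxel_spacing = as.numeric(voxel_spacing),
                 class_params = class_params,
                 perturbation = perturbation,
                 master_seed = as.integer(master_seed)),
            class = "cohort_config")
}

# deterministic sub-seed derivation, kept below 2^31
derive_seed <- function(master, k) {
  as.integer((as.numeric(master) * 48271 + as.numeric(k) * 110351) %% 2147483629 + 1)
}

# separable Gaussian smoothing with edge replication
gauss_smooth_3d <- function(arr, sigma_vox) {
  if (sigma_vox <= 0) return(arr)
  half <- max(1L, ceiling(3 * sigma_vox))
  kern <- stats::dnorm(seq(-half, half), sd = sigma_vox)
  kern <- kern / sum(kern)
  for (axis in 1:3) {
    d <- dim(arr)
    n <- d[axis]
    pad_lo <- slice_axis(arr, axis, rep(1L, half))
    pad_hi <- slice_axis(arr, axis, rep(n, half))
    padded <- abind_axis(pad_lo, arr, pad_hi, axis)
    out <- array(0, dim = d)
    for (t in seq_along(kern)) {
      out <- out + kern[t] * slice_axis(padded, axis, seq.int(t, t + n - 1L))
    }
    arr <- out
  }
  arr
}

slice_axis <- function(arr, axis, idx) {
  switch(axis,
         arr[idx, , , drop = FALSE],
         arr[, idx, , drop = FALSE],
         arr[, , idx, drop = FALSE])
}

abind_axis <- function(a, b, c, axis) {
  da <- dim(a); db <- dim(b); dc <- dim(c)
  d <- db; d[axis] <- da[axis] + db[axis] + dc[axis]
  out <- array(0, dim = d)
  n1 <- da[axis]; n2 <- db[axis]; n3 <- dc[axis]
  switch(axis, {
    out[seq_len(n1), , ] <- a; out[n1 + seq_len(n2), , ] <- b
    out[n1 + n2 + seq_len(n3), , ] <- c
  }, {
    out[, seq_len(n1), ] <- a; out[, n1 + seq_len(n2), ] <- b
    out[, n1 + n2 + seq_len(n3), ] <- c
  }, {
    out[, , seq_len(n1)] <- a; out[, , n1 + seq_len(n2)] <- b
    out[, , n1 + n2 + seq_len(n3)] <- c
  })
  out
}

# deterministic depth profile: attenuated signal with faint horizontal layers
background_profile <- function(z_mm) {
  40 + 120 * exp(-z_mm / 0.8) + 15 * sin(2 * pi * z_mm / 0.4)
}

#' Generate one synthetic OCT lesion volume with its ROI mask
#'
#' Renders a depth-attenuated layered background and an axis-aligned
#' ellipsoidal lesion whose interior is
#' `mean_intensity + texture_contrast * G + N(0, intensity_sd)`, with `G` a
#' unit-variance Gaussian random field obtained by smoothing white noise with
#' a Gaussian kernel of width `texture_correlation_length`. Output is clipped
#' to \[0, 255\] and rounded to 8-bit precision. The mask marks exactly the
#' voxels whose centres fall inside the ellipsoid.
#'
#' @param params A [lesion_class_params()].
#' @param shape Volume shape in voxels (x, y, z).
#' @param spacing Voxel spacing, mm.
#' @param seed Integer seed; identical inputs render bit-identical outputs.
#' @param center Lesion centre in mm (default: volume centre).
#' @param transform Optional list(`shift` mm length-3, `axial_scale` scalar)
#'   applied to the lesion while sampling the same texture field, used to
#'   build retest scans.
#' @return List with elements `volume` ([oct_volume()]) and `mask`
#'   ([oct_mask()]).
#' @export
generate_lesion_volume <- function(params, shape = c(128L, 128L, 64L),
                                   spacing = c(0.05, 0.05, 0.05), seed = 1L,
                                   center = NULL, transform = NULL) {
  stopifnot(inherits(params, "lesion_class_params"))
  shape <- as.integer(shape); spacing <- as.numeric(spacing)
  extent <- (shape - 1) * spacing
  center <- center %||% (extent / 2)
  shift <- (transform$shift) %||% c(0, 0, 0)
  ascale <- (transform$axial_scale) %||% 1
  axes <- params$ellipsoid_semi_axes
  axes_t <- c(axes[1], axes[2], axes[3] * ascale)
  center_t <- center + shift
  if (any(center_t - axes_t < 0) || any(center_t + axes_t > extent)) {
    abort(sprintf("lesion (centre %s mm, semi-axes %s mm) exceeds volume bounds %s mm",
                  paste(round(center_t, 2), collapse = ","),
                  paste(round(axes_t, 2), collapse = ","),
                  paste(round(extent, 2), collapse = ",")))
  }

  # texture-field support: base ellipsoid bounding box plus margin, so a
  # translated/compressed retest still samples inside the same field
  margin_vox <- ceiling(pmax(3 * params$texture_correlation_length, 0.5) / spacing) + 2L
  lo <- pmax(1L, floor((center - axes) / spacing) + 1L - margin_vox)
  hi <- pmin(shape, ceiling((center + axes) / spacing) + 1L + margin_vox)
  bdim <- hi - lo + 1L
  # the box size must not depend on the transform (the field draws would
  # change), so large transforms that escape it are rejected instead
  box_lo <- (lo - 1L) * spacing; box_hi <- (hi - 1L) * spacing
  if (any(center_t - axes_t < box_lo - 1e-9 & lo > 1L) ||
      any(center_t + axes_t > box_hi + 1e-9 & hi < shape)) {
    abort("transform moves the lesion outside its texture-field support")
  }

  set.seed(seed)
  white <- array(rnorm(prod(bdim)), dim = bdim)
  field <- gauss_smooth_3d(white, params$texture_correlation_length / mean(spacing))
  fsd <- sd(as.vector(field))
  if (fsd > 0) field <- (field - mean(field)) / fsd
  noise <- array(rnorm(prod(bdim)), dim = bdim)

  # background from the deterministic depth profile
  zprof <- background_profile((seq_len(shape[3]) - 1) * spacing[3])
  vol <- array(rep(zprof, each = shape[1] * shape[2]), dim = shape)

  # voxels inside the (transformed) ellipsoid, restricted to the field box
  xs <- (seq.int(lo[1], hi[1]) - 1) * spacing[1]
  ys <- (seq.int(lo[2], hi[2]) - 1) * spacing[2]
  zs <- (seq.int(lo[3], hi[3]) - 1) * spacing[3]
  dx2 <- ((xs - center_t[1]) / axes_t[1])^2
  dy2 <- ((ys - center_t[2]) / axes_t[2])^2
  dz2 <- ((zs - center_t[3]) / axes_t[3])^2
  inside <- outer(outer(dx2, dy2, "+"), dz2, "+") <= 1
  idx <- which(inside, arr.ind = TRUE)

  if (nrow(idx) > 0) {
    # sample the field at the pre-image of each lesion voxel (nearest neighbour)
    px <- xs[idx[, 1]]; py <- ys[idx[, 2]]; pz <- zs[idx[, 3]]
    qx <- px - shift[1]
    qy <- py - shift[2]
    qz <- center[3] + (pz - center_t[3]) / ascale
    fi <- pmin(pmax(round(qx / spacing[1]) + 1L - lo[1] + 1L, 1L), bdim[1])
    fj <- pmin(pmax(round(qy / spacing[2]) + 1L - lo[2] + 1L, 1L), bdim[2])
    fk <- pmin(pmax(round(qz / spacing[3]) + 1L - lo[3] + 1L, 1L), bdim[3])
    flin <- cbind(fi, fj, fk)
    vals <- params$mean_intensity +
      params$texture_contrast * field[flin] +
      params$intensity_sd * noise[flin]
    sub <- vol[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]]
    sub[idx] <- vals
    vol[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- sub
  }

  mask <- array(0L, dim = shape)
  msub <- array(0L, dim = bdim)
  msub[inside] <- 1L
  mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- msub

  vol <- array(as.integer(round(clamp255(vol))), dim = shape)
  list(volume = oct_volume(vol, spacing = spacing),
       mask = oct_mask(mask, spacing = spacing))
}

# multiplicative log-normal speckle, mean-one; log-SD scaled so that the
# induced gray-value SD at mid-scale (128) is about speckle_sd
apply_speckle <- function(volume, speckle_sd, seed) {
  if (speckle_sd <= 0) return(volume)
  sig <- speckle_sd / 128
  set.seed(seed)
  z <- array(rnorm(length(volume$values)), dim = dim(volume$values))
  v <- volume$values * exp(sig * z - sig^2 / 2)
  oct_volume(array(as.integer(round(clamp255(v))), dim = dim(v)),
             spacing = volume$spacing, origin = volume$origin)
}

#' Generate a test-retest scan pair of one lesion
#'
#' The test scan renders the lesion; the retest scan re-renders the same
#' underlying texture field after a random rigid translation and axial
#' compression drawn from `perturbation`, with independent multiplicative
#' speckle applied to each scan. The retest mask is re-derived from the
#' transformed ellipsoid, so shape features may legitimately differ between
#' timepoints. With all perturbation SDs zero the retest is voxel-identical
#' to the test.
#'
#' @inheritParams generate_lesion_volume
#' @param perturbation A [retest_perturbation()].
#' @return List with elements `test` and `retest`, each a list
#'   `(volume, mask)`, plus the drawn `shift` and `axial_scale`.
#' @export
generate_retest_pair <- function(params, perturbation = retest_perturbation(),
                                 shape = c(128L, 128L, 64L),
                                 spacing = c(0.05, 0.05, 0.05), seed = 1L,
                                 center = NULL) {
  stopifnot(inherits(perturbation, "retest_perturbation"))
  seed_lesion <- derive_seed(seed, 1L)
  seed_jitter <- derive_seed(seed, 2L)
  seed_sp1 <- derive_seed(seed, 3L)
  seed_sp2 <- derive_seed(seed, 4L)

  test <- generate_lesion_volume(params, shape, spacing, seed = seed_lesion,
                                 center = center)
  set.seed(seed_jitter)
  shift <- rnorm(3, 0, perturbation$translation_sd)
  ascale <- 1 + rnorm(1, 0, perturbation$axial_scale_sd)
  ascale <- min(max(ascale, 0.75), 1.25)
  identity_tf <- all(shift == 0) && ascale == 1
  retest <- if (identity_tf) {
    list(volume = test$volume, mask = test$mask)
  } else {
    generate_lesion_volume(params, shape, spacing, seed = seed_lesion,
                           center = center,
                           transform = list(shift = shift, axial_scale = ascale))
  }
  test$volume <- apply_speckle(test$volume, perturbation$speckle_sd, seed_sp1)
  retest$volume <- apply_speckle(retest$volume, perturbation$speckle_sd, seed_sp2)
  list(test = test, retest = retest, shift = shift, axial_scale = ascale)
}

# per-lesion jitter of the class parameters (between-lesion heterogeneity)
jitter_params <- function(params, seed) {
  set.seed(seed)
  ax <- sort(params$ellipsoid_semi_axes * runif(3, 0.85, 1.15), decreasing = TRUE)
  mi <- min(max(params$mean_intensity + rnorm(1, 0, 8), 20), 235)
  cl <- params$texture_correlation_length * runif(1, 0.8, 1.25)
  lesion_class_params(params$class_label,
                      texture_correlation_length = cl,
                      texture_contrast = params$texture_contrast,
                      mean_intensity = mi,
                      intensity_sd = params$intensity_sd,
                      ellipsoid_semi_axes = ax)
}

#' Generate the synthetic study cohorts
#'
#' Builds the manifest for both study arms: the test-retest repeatability
#' cohort (`n_subjects * lesions_per_subject` lesions, two timepoints each)
#' and the three-class classification cohort. Per-lesion parameters are
#' jittered around the class defaults so lesions are heterogeneous; each
#' manifest row carries the seed from which its scan is rendered, so scans
#' can be rendered lazily with [render_scan()] or written to NRRD with
#' [write_cohort()].
#'
#' @param config A [cohort_config()].
#' @return An `oct_cohort` object: list with `manifest` (tibble with columns
#'   scan_id, subject_id, lesion_id, timepoint, class_label, cohort, seed,
#'   gt_mean_intensity) and `config`.
#' @examples
#' coh <- generate_study_cohorts(cohort_config(n_subjects = 1))
#' nrow(coh$manifest)
#' @export
generate_study_cohorts <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  ms <- config$master_seed
  rows <- list()
  k <- 0L
  # test-retest arm: nevi scanned twice
  for (s in seq_len(config$n_subjects)) {
    for (l in seq_len(config$lesions_per_subject)) {
      k <- k + 1L
      lesion_id <- sprintf("N%03d", k)
      lseed <- derive_seed(ms, k)
      pj <- jitter_params(config$class_params$nevus, lseed)
      for (tp in 1:2) {
        rows[[length(rows) + 1L]] <- tibble(
          scan_id = sprintf("%s_T%d", lesion_id, tp),
          subject_id = sprintf("S%03d", s), lesion_id = lesion_id,
          timepoint = tp, class_label = "nevus", cohort = "retest",
          seed = lseed, gt_mean_intensity = pj$mean_intensity)
      }
    }
  }
  # classification arm
  j <- 0L
  for (cl in names(config$class_counts)) {
    n_cl <- config$class_counts[[cl]]
    for (i in seq_len(n_cl)) {
      j <- j + 1L
      lseed <- derive_seed(ms, 10000L + j)
      pj <- jitter_params(config$class_params[[cl]], lseed)
      rows[[length(rows) + 1L]] <- tibble(
        scan_id = sprintf("C%03d_%s", j, cl),
        subject_id = sprintf("P%03d", j), lesion_id = sprintf("C%03d", j),
        timepoint = 1L, class_label = cl, cohort = "classification",
        seed = lseed, gt_mean_intensity = pj$mean_intensity)
    }
  }
  structure(list(manifest = dplyr::bind_rows(rows), config = config),
            class = "oct_cohort")
}

#' @export
print.oct_cohort <- function(x, ...) {
  n <- table(x$manifest$cohort)
  cat(sprintf("<oct_cohort> %d scans (%s)\n", nrow(x$manifest),
              paste(sprintf("%s: %d", names(n), n), collapse = ", ")))
  invisible(x)
}

#' Render one scan of a synthetic cohort
#'
#' Renders the volume and mask for a manifest row, reproducing the same scan
#' for the same cohort configuration and scan id.
#'
#' @param cohort An `oct_cohort` from [generate_study_cohorts()].
#' @param scan_id A scan id present in the manifest.
#' @return List `(volume, mask)`.
#' @export
render_scan <- function(cohort, scan_id) {
  stopifnot(inherits(cohort, "oct_cohort"))
  row <- cohort$manifest[cohort$manifest$scan_id == scan_id, ]
  if (nrow(row) != 1L) abort(sprintf("scan id not found in manifest: %s", scan_id))
  cfg <- cohort$config
  pj <- jitter_params(cfg$class_params[[row$class_label]], row$seed)
  if (row$cohort == "retest") {
    pair <- generate_retest_pair(pj, cfg$perturbation, cfg$volume_shape,
                                 cfg$voxel_spacing, seed = row$seed)
    if (row$timepoint == 1L) pair$test else pair$retest
  } else {
    scan <- generate_lesion_volume(pj, cfg$volume_shape, cfg$voxel_spacing,
                                   seed = derive_seed(row$seed, 1L))
    scan$volume <- apply_speckle(scan$volume, cfg$perturbation$speckle_sd,
                                 derive_seed(row$seed, 3L))
    scan
  }
}

#' Write a synthetic cohort to NRRD files plus a CSV manifest
#'
#' Writes `<scan_id>.nrrd` and `<scan_id>_mask.nrrd` per scan and
#' `manifest.csv` into `dir`.
#'
#' @inheritParams render_scan
#' @param dir Output directory (created if missing).
#' @param scan_ids Subset of scans to write (default: all).
#' @return Invisibly, the manifest with `volume_path`/`mask_path` columns.
#' @export
write_cohort <- function(cohort, dir, scan_ids = NULL) {
  stopifnot(inherits(cohort, "oct_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  man <- cohort$manifest
  if (!is.null(scan_ids)) man <- man[man$scan_id %in% scan_ids, ]
  man$volume_path <- file.path(dir, paste0(man$scan_id, ".nrrd"))
  man$mask_path <- file.path(dir, paste0(man$scan_id, "_mask.nrrd"))
  for (i in seq_len(nrow(man))) {
    scan <- render_scan(cohort, man$scan_id[i])
    write_nrrd(scan$volume, man$volume_path[i])
    write_nrrd(oct_volume(scan$mask$values, scan$mask$spacing, scan$mask$origin),
               man$mask_path[i])
  }
  write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(man)
}
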