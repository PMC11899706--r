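# Independent brute-force enumerators used as oracles for the C++ texture
# matrix builders, plus small fixture constructors. These deliberately use
# naive per-voxel loops, not the package's code paths.

dir_offsets <- function() {
  rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
        c(1, 1, 0), c(1, -1, 0), c(1, 0, 1), c(1, 0, -1),
        c(0, 1, 1), c(0, 1, -1),
        c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1))
}

all_offsets_26 <- function() {
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  as.matrix(g[!(g$dx == 0 & g$dy == 0 & g$dz == 0), ])
}

in_bounds <- function(p, d) all(p >= 1) && all(p <= d)

# exhaustive pair counting for the symmetric co-occurrence matrix
bf_glcm <- function(lev, ng) {
  d <- dim(lev)
  dirs <- dir_offsets()
  out <- array(0, c(ng, ng, nrow(dirs)))
  for (k in seq_len(nrow(dirs))) {
    for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
      li <- lev[x, y, z]
      if (li <= 0) next
      p2 <- c(x, y, z) + dirs[k, ]
      if (!in_bounds(p2, d)) next
      lj <- lev[p2[1], p2[2], p2[3]]
      if (lj <= 0) next
      out[li, lj, k] <- out[li, lj, k] + 1
      out[lj, li, k] <- out[lj, li, k] + 1
    }
  }
  out
}

# run scanning: walk each line of each direction, rle the levels
bf_glrlm <- function(lev, ng) {
  d <- dim(lev)
  dirs <- dir_offsets()
  maxlen <- max(d)
  out <- array(0, c(ng, maxlen, nrow(dirs)))
  for (k in seq_len(nrow(dirs))) {
    dk <- dirs[k, ]
    for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
      p <- c(x, y, z)
      prev <- p - dk
      li <- lev[x, y, z]
      if (li <= 0) next
      if (in_bounds(prev, d) && lev[prev[1], prev[2], prev[3]] == li) next
      len <- 1
      nxt <- p + dk
      while (in_bounds(nxt, d) && lev[nxt[1], nxt[2], nxt[3]] == li) {
        len <- len + 1
        nxt <- nxt + dk
      }
      out[li, len, k] <- out[li, len, k] + 1
    }
  }
  out
}

# flood fill with a queue over the 26-neighbourhood
bf_glszm <- function(lev, ng) {
  d <- dim(lev)
  seen <- array(FALSE, d)
  offs <- all_offsets_26()
  zones <- list()
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    if (seen[x, y, z] || lev[x, y, z] <= 0) next
    li <- lev[x, y, z]
    queue <- list(c(x, y, z))
    seen[x, y, z] <- TRUE
    size <- 0
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      size <- size + 1
      for (o in seq_len(nrow(offs))) {
        q <- p + offs[o, ]
        if (in_bounds(q, d) && !seen[q[1], q[2], q[3]] &&
            lev[q[1], q[2], q[3]] == li) {
          seen[q[1], q[2], q[3]] <- TRUE
          queue[[length(queue) + 1]] <- q
        }
      }
    }
    zones[[length(zones) + 1]] <- c(level = li, size = size)
  }
  do.call(rbind, zones)
}

# per-voxel neighbour counting for the dependence matrix (alpha = 0)
bf_gldm <- function(lev, ng) {
  d <- dim(lev)
  offs <- all_offsets_26()
  out <- matrix(0, ng, 27)
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    li <- lev[x, y, z]
    if (li <= 0) next
    dep <- 0
    for (o in seq_len(nrow(offs))) {
      q <- c(x, y, z) + offs[o, ]
      if (in_bounds(q, d) && lev[q[1], q[2], q[3]] == li) dep <- dep + 1
    }
    out[li, dep + 1] <- out[li, dep + 1] + 1
  }
  out
}

# per-voxel neighbour means for the gray-tone difference table
bf_ngtdm <- function(lev, ng) {
  d <- dim(lev)
  offs <- all_offsets_26()
  n_i <- numeric(ng); s_i <- numeric(ng)
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    li <- lev[x, y, z]
    if (li <= 0) next
    nb <- c()
    for (o in seq_len(nrow(offs))) {
      q <- c(x, y, z) + offs[o, ]
      if (in_bounds(q, d) && lev[q[1], q[2], q[3]] > 0) {
        nb <- c(nb, lev[q[1], q[2], q[3]])
      }
    }
    if (length(nb)) {
      n_i[li] <- n_i[li] + 1
      s_i[li] <- s_i[li] + abs(li - mean(nb))
    }
  }
  cbind(n_i, s_i)
}

# Lin's CCC by direct moment computation, an independent route from ccc()
bf_ccc <- function(x, y) {
  n <- length(x)
  m1 <- sum(x) / n; m2 <- sum(y) / n
  v1 <- sum((x - m1)^2) / n; v2 <- sum((y - m2)^2) / n
  r <- suppressWarnings(cor(x, y))
  if (is.na(r)) return(NA_real_)
  2 * r * sqrt(v1) * sqrt(v2) / (v1 + v2 + (m1 - m2)^2)
}

# random small quantized ROI embedded in a quantized_roi-compatible object
random_tiny_qroi <- function(max_dim = 5L, ng = 4L) {
  d <- sample.int(max_dim, 3, replace = TRUE)
  d <- pmax(d, c(2L, 1L, 1L))
  roi <- array(runif(prod(d)) < 0.7, d)
  if (!any(roi)) roi[1] <- TRUE
  lev <- array(0L, d)
  lev[roi] <- sample.int(ng, sum(roi), replace = TRUE)
  structure(list(levels = lev, ng = ng, bin_width = 1, anchor = 0,
                 n_voxels = sum(roi), spacing = c(1, 1, 1)),
            class = "quantized_roi")
}

# small lesion scan that renders fast (used across test files)
small_scan <- function(seed = 1, class_label = "nevus",
                       axes = c(0.45, 0.35, 0.25), shape = c(40L, 36L, 28L)) {
  params <- lesion_class_params(class_label, ellipsoid_semi_axes = axes)
  generate_lesion_volume(params, shape = shape, spacing = c(0.05, 0.05, 0.05),
                         seed = seed)
}

# reduced-scale cohort configuration used where geometric size is not the
# quantity under test (composition stays study-like unless overridden)
small_cohort_config <- function(n_subjects = 6L, lesions_per_subject = 2L,
                                class_counts = c(bcc = 14L, bowen = 10L, nevus = 12L),
                                perturbation = retest_perturbation(),
                                master_seed = 42L) {
  scale_axes <- function(p) {
    lesion_class_params(p$class_label,
                        texture_correlation_length = p$texture_correlation_length,
                        texture_contrast = p$texture_contrast,
                        mean_intensity = p$mean_intensity,
                        intensity_sd = p$intensity_sd,
                        ellipsoid_semi_axes = p$ellipsoid_semi_axes * 0.38)
  }
  cohort_config(
    n_subjects = n_subjects, lesions_per_subject = lesions_per_subject,
    class_counts = class_counts,
    volume_shape = c(56L, 56L, 36L), voxel_spacing = c(0.05, 0.05, 0.05),
    class_params = list(nevus = scale_axes(lesion_class_params("nevus")),
                        bcc = scale_axes(lesion_class_params("bcc")),
                        bowen = scale_axes(lesion_class_params("bowen"))),
    perturbation = perturbation, master_seed = master_seed)
}

# canonical ordering of a (level, size) zone table for multiset comparison
sort_zone_table <- function(z) {
  df <- as.data.frame(z)
  colnames(df) <- c("level", "size")
  df <- df[order(df$level, df$size), ]
  rownames(df) <- NULL
  df
}
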