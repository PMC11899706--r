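#' Texture features from gray-level matrices
#'
#' Five families of texture features computed from a fixed-bin-size
#' [quantize_fbs()] discretization of the ROI:
#'
#' * `glcm_features()` — 24 features from symmetric gray-level co-occurrence
#'   matrices at distance 1 over the 13 unique 3D directions, computed per
#'   direction on the normalized matrix and averaged over directions.
#' * `glrlm_features()` — 16 features from run-length matrices (runs are
#'   maximal same-level collinear ROI segments) over the same 13 directions,
#'   averaged over directions.
#' * `glszm_features()` — 16 features from the size-zone matrix (zones are
#'   26-connected components of equal level); direction-free.
#' * `gldm_features()` — 14 features from the dependence matrix with
#'   `alpha = 0`: a 26-neighbour is dependent when its level equals the
#'   centre's, and the dependence size is 1 plus the dependent-neighbour
#'   count.
#' * `ngtdm_features()` — 5 features (Coarseness, Contrast, Busyness,
#'   Complexity, Strength) from per-level counts `n_i` and summed absolute
#'   differences `s_i` between each voxel's level and the mean level of its
#'   valid 26-neighbours.
#'
#' Degenerate conventions (constant, single-level ROI): GLCM `Correlation`
#' and `MCC` are defined as 1, NGTDM `Coarseness` is capped at 1e6, NGTDM
#' `Contrast`/`Busyness`/`Strength` are 0.
#'
#' @param qroi A `quantized_roi` from [quantize_fbs()].
#' @return Named numeric vector per family, prefixed with the family tag.
#' @name texture_features
NULL

EPS <- .Machine$double.eps

#' @rdname texture_features
#' @export
glcm_features <- function(qroi) {
  stopifnot(inherits(qroi, "quantized_roi"))
  ng <- qroi$ng
  counts <- .cpp_glcm_counts(qroi$levels, ng)
  per_dir <- apply(counts, 3, glcm_features_one, ng = ng)
  if (is.null(dim(per_dir))) per_dir <- matrix(per_dir, nrow = 1)
  avg <- rowMeans(per_dir, na.rm = TRUE)
  setNames(avg, paste0("glcm_", rownames(per_dir) %||% glcm_feature_names()))
}

glcm_feature_names <- function() {
  c("Autocorrelation", "JointAverage", "ClusterProminence", "ClusterShade",
    "ClusterTendency", "Contrast", "Correlation", "DifferenceAverage",
    "DifferenceEntropy", "DifferenceVariance", "JointEnergy", "JointEntropy",
    "Imc1", "Imc2", "Idm", "Idmn", "Id", "Idn", "InverseVariance",
    "MaximumProbability", "SumAverage", "SumEntropy", "SumSquares", "MCC")
}

glcm_features_one <- function(cmat, ng) {
  cmat <- matrix(cmat, ng, ng)
  tot <- sum(cmat)
  nm <- glcm_feature_names()
  if (tot == 0) {
    # no voxel pairs along this direction (e.g. single-voxel ROI)
    out <- rep(NA_real_, length(nm))
    names(out) <- nm
    return(out)
  }
  p <- cmat / tot
  i <- matrix(seq_len(ng), ng, ng)
  j <- t(i)
  px <- rowSums(p)                       # == colSums(p) by symmetry
  ux <- sum(seq_len(ng) * px)
  sx2 <- sum((seq_len(ng) - ux)^2 * px)
  sx <- sqrt(sx2)
  # diagonal-band (difference) and anti-diagonal (sum) marginals
  kd <- 0:(ng - 1)
  pd <- as.vector(rowsum(as.vector(p), as.vector(abs(i - j))))
  ks <- 2:(2 * ng)
  ps <- as.vector(rowsum(as.vector(p), as.vector(i + j)))
  da <- sum(kd * pd)
  hxy <- -sum(p * log2(p + EPS))
  pxpy <- outer(px, px)
  hxy1 <- -sum(p * log2(pxpy + EPS))
  hxy2 <- -sum(pxpy * log2(pxpy + EPS))
  hx <- -sum(px * log2(px + EPS))
  corr <- if (sx2 > 0) (sum(i * j * p) - ux^2) / (sx * sx) else 1
  mcc <- glcm_mcc(p, px)
  vals <- c(
    sum(i * j * p),
    ux,
    sum((i + j - 2 * ux)^4 * p),
    sum((i + j - 2 * ux)^3 * p),
    sum((i + j - 2 * ux)^2 * p),
    sum((i - j)^2 * p),
    corr,
    da,
    -sum(pd * log2(pd + EPS)),
    sum((kd - da)^2 * pd),
    sum(p^2),
    hxy,
    if (hx > 0) (hxy - hxy1) / hx else 0,
    sqrt(pmax(0, 1 - exp(-2 * (hxy2 - hxy)))),
    sum(pd / (1 + kd^2)),
    sum(pd / (1 + (kd / ng)^2)),
    sum(pd / (1 + kd)),
    sum(pd / (1 + kd / ng)),
    sum(pd[-1] / kd[-1]^2),
    max(p),
    sum(ks * ps),
    -sum(ps * log2(ps + EPS)),
    sum((i - ux)^2 * p),
    mcc)
  setNames(vals, nm)
}

glcm_mcc <- function(p, px) {
  keep <- px > 0
  if (sum(keep) < 2) return(1)
  pk <- p[keep, keep, drop = FALSE]
  pxk <- px[keep]
  # Q(a,b) = sum_k p(a,k) p(b,k) / (px(a) py(k))
  q <- (pk / pxk) %*% t(sweep(pk, 2, pxk, "/"))
  ev <- sort(Re(eigen(q, only.values = TRUE)$values), decreasing = TRUE)
  sqrt(max(0, ev[2]))
}

#' @rdname texture_features
#' @export
glrlm_features <- function(qroi) {
  stopifnot(inherits(qroi, "quantized_roi"))
  ng <- qroi$ng
  counts <- .cpp_glrlm_counts(qroi$levels, ng)
  np <- qroi$n_voxels
  nd <- dim(counts)[3]
  per_dir <- vapply(seq_len(nd),
                    function(d) slm_features(matrix(counts[, , d], ng), np),
                    numeric(16))
  avg <- rowMeans(per_dir, na.rm = TRUE)
  setNames(avg, paste0("glrlm_", glrlm_feature_names()))
}

glrlm_feature_names <- function() {
  c("ShortRunEmphasis", "LongRunEmphasis", "GrayLevelNonUniformity",
    "GrayLevelNonUniformityNormalized", "RunLengthNonUniformity",
    "RunLengthNonUniformityNormalized", "RunPercentage", "GrayLevelVariance",
    "RunVariance", "RunEntropy", "LowGrayLevelRunEmphasis",
    "HighGrayLevelRunEmphasis", "ShortRunLowGrayLevelEmphasis",
    "ShortRunHighGrayLevelEmphasis", "LongRunLowGrayLevelEmphasis",
    "LongRunHighGrayLevelEmphasis")
}

glszm_feature_names <- function() {
  c("SmallAreaEmphasis", "LargeAreaEmphasis", "GrayLevelNonUniformity",
    "GrayLevelNonUniformityNormalized", "SizeZoneNonUniformity",
    "SizeZoneNonUniformityNormalized", "ZonePercentage", "GrayLevelVariance",
    "ZoneVariance", "ZoneEntropy", "LowGrayLevelZoneEmphasis",
    "HighGrayLevelZoneEmphasis", "SmallAreaLowGrayLevelEmphasis",
    "SmallAreaHighGrayLevelEmphasis", "LargeAreaLowGrayLevelEmphasis",
    "LargeAreaHighGrayLevelEmphasis")
}

# shared 16-feature battery for run-length-like matrices M(level, size)
slm_features <- function(m, np) {
  ns <- sum(m)                 # number of runs / zones
  if (ns == 0) return(rep(NA_real_, 16))
  ng <- nrow(m)
  i <- matrix(seq_len(ng), ng, ncol(m))
  s <- t(matrix(seq_len(ncol(m)), ncol(m), ng))
  p <- m / ns
  mu_i <- sum(i * p)
  mu_s <- sum(s * p)
  c(sum(m / s^2) / ns,
    sum(m * s^2) / ns,
    sum(rowSums(m)^2) / ns,
    sum(rowSums(m)^2) / ns^2,
    sum(colSums(m)^2) / ns,
    sum(colSums(m)^2) / ns^2,
    ns / np,
    sum((i - mu_i)^2 * p),
    sum((s - mu_s)^2 * p),
    -sum(p * log2(p + EPS)),
    sum(m / i^2) / ns,
    sum(m * i^2) / ns,
    sum(m / (i^2 * s^2)) / ns,
    sum(m * i^2 / s^2) / ns,
    sum(m * s^2 / i^2) / ns,
    sum(m * i^2 * s^2) / ns)
}

#' @rdname texture_features
#' @export
glszm_features <- function(qroi) {
  stopifnot(inherits(qroi, "quantized_roi"))
  zones <- .cpp_glszm_zones(qroi$levels, qroi$ng)
  smax <- max(zones[, "size"])
  m <- matrix(0, qroi$ng, smax)
  for (r in seq_len(nrow(zones))) {
    m[zones[r, "level"], zones[r, "size"]] <- m[zones[r, "level"], zones[r, "size"]] + 1
  }
  setNames(slm_features(m, qroi$n_voxels), paste0("glszm_", glszm_feature_names()))
}

#' @rdname texture_features
#' @export
gldm_features <- function(qroi) {
  stopifnot(inherits(qroi, "quantized_roi"))
  m <- .cpp_gldm_counts(qroi$levels, qroi$ng)
  m <- m[, seq_len(max(which(colSums(m) > 0))), drop = FALSE]
  nz <- sum(m)                 # == number of ROI voxels
  ng <- nrow(m)
  i <- matrix(seq_len(ng), ng, ncol(m))
  j <- t(matrix(seq_len(ncol(m)), ncol(m), ng))
  p <- m / nz
  mu_i <- sum(i * p)
  mu_j <- sum(j * p)
  vals <- c(sum(m / j^2) / nz,
            sum(m * j^2) / nz,
            sum(rowSums(m)^2) / nz,
            sum(colSums(m)^2) / nz,
            sum(colSums(m)^2) / nz^2,
            sum((i - mu_i)^2 * p),
            sum((j - mu_j)^2 * p),
            -sum(p * log2(p + EPS)),
            sum(m / i^2) / nz,
            sum(m * i^2) / nz,
            sum(m / (i^2 * j^2)) / nz,
            sum(m * i^2 / j^2) / nz,
            sum(m * j^2 / i^2) / nz,
            sum(m * i^2 * j^2) / nz)
  setNames(vals, paste0("gldm_", gldm_feature_names()))
}

gldm_feature_names <- function() {
  c("SmallDependenceEmphasis", "LargeDependenceEmphasis",
    "GrayLevelNonUniformity", "DependenceNonUniformity",
    "DependenceNonUniformityNormalized", "GrayLevelVariance",
    "DependenceVariance", "DependenceEntropy", "LowGrayLevelEmphasis",
    "HighGrayLevelEmphasis", "SmallDependenceLowGrayLevelEmphasis",
    "SmallDependenceHighGrayLevelEmphasis",
    "LargeDependenceLowGrayLevelEmphasis",
    "LargeDependenceHighGrayLevelEmphasis")
}

#' @rdname texture_features
#' @export
ngtdm_features <- function(qroi) {
  stopifnot(inherits(qroi, "quantized_roi"))
  tab <- .cpp_ngtdm_counts(qroi$levels, qroi$ng)
  n_i <- tab[, 1]
  s_i <- tab[, 2]
  nv <- sum(n_i)
  lev <- seq_len(qroi$ng)
  present <- n_i > 0
  p_i <- n_i / nv
  ngp <- sum(present)
  ii <- lev[present]; pp <- p_i[present]; ss <- s_i[present]
  ps <- sum(p_i * s_i)
  coarseness <- if (ps > 0) min(1 / ps, 1e6) else 1e6
  contrast <- if (ngp > 1) {
    (sum(outer(pp, pp) * outer(ii, ii, function(a, b) (a - b)^2)) /
       (ngp * (ngp - 1))) * (sum(s_i) / nv)
  } else 0
  busy_den <- sum(abs(outer(ii * pp, ii * pp, "-")))
  busyness <- if (busy_den > 0) ps / busy_den else 0
  # complexity: |i-j| (p_i s_i + p_j s_j) / (p_i + p_j), pairs with p > 0
  cij <- outer(ii, ii, function(a, b) abs(a - b)) *
    (outer(pp * ss, pp * ss, "+") / outer(pp, pp, "+"))
  complexity <- sum(cij) / nv
  strength <- if (sum(s_i) > 0) {
    sum(outer(pp, pp, "+") * outer(ii, ii, function(a, b) (a - b)^2)) / sum(s_i)
  } else 0
  setNames(c(coarseness, contrast, busyness, complexity, strength),
           paste0("ngtdm_", c("Coarseness", "Contrast", "Busyness",
                              "Complexity", "Strength")))
}
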