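# Texture feature families over a discretized ROI. Matrix construction
# is in C++; feature formulas follow the standard (IBSI-style)
# definitions. Every 0/0 degenerates to a documented constant (see the
# per-feature guards), never NaN, so downstream matrices stay finite.

glcm_single <- function(P, ng) {
  # P: symmetric co-occurrence matrix, normalized to sum 1
  i <- row(P); j <- col(P)
  px <- rowSums(P)
  mu <- sum(i * P)                       # symmetric: mu_x = mu_y
  sig2 <- sum((i - mu)^2 * P)
  sig <- sqrt(sig2)
  # diagonal (difference) and cross (sum) distributions; every value of
  # |i-j| in 0..ng-1 and of i+j in 2..2ng occurs in the full index grid,
  # so rowsum returns dense vectors in sorted order
  k_d <- 0:(ng - 1)
  p_d <- as.numeric(rowsum(as.vector(P), as.vector(abs(i - j))))
  k_s <- 2:(2 * ng)
  p_s <- as.numeric(rowsum(as.vector(P), as.vector(i + j)))
  nz <- P > 0
  hxy <- -sum(P[nz] * log2(P[nz]))
  pxpy <- outer(px, px)
  ok <- nz & pxpy > 0
  hxy1 <- -sum(P[ok] * log2(pxpy[ok]))
  nz2 <- pxpy > 0
  hxy2 <- -sum(pxpy[nz2] * log2(pxpy[nz2]))
  hx <- -sum(px[px > 0] * log2(px[px > 0]))
  imc1 <- if (hx > 0) (hxy - hxy1) / hx else 0
  imc2 <- if (hxy2 >= hxy) sqrt(1 - exp(-2 * (hxy2 - hxy))) else 0
  # MCC from the transition-normalized matrix; 1 when degenerate
  mcc <- 1
  if (ng > 1 && sig2 > 0) {
    occ <- which(px > 0)
    Psub <- P[occ, occ, drop = FALSE]
    pxs <- px[occ]
    # Q[a,b] = sum_k P[a,k] P[b,k] / (px[a] px[k])
    Q <- (Psub / pxs) %*% t(sweep(Psub, 2, pxs, `/`))
    evq <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    mcc <- if (length(evq) >= 2) sqrt(max(min(evq[2], 1), 0)) else 1
  }
  da <- sum(k_d * p_d)
  pd_nz <- p_d > 0
  ps_nz <- p_s > 0
  corr <- if (sig2 > 0) (sum(i * j * P) - mu^2) / sig2 else 1
  c(Autocorrelation = sum(i * j * P),
    ClusterProminence = sum((i + j - 2 * mu)^4 * P),
    ClusterShade = sum((i + j - 2 * mu)^3 * P),
    ClusterTendency = sum((i + j - 2 * mu)^2 * P),
    Contrast = sum((i - j)^2 * P),
    Correlation = corr,
    DifferenceAverage = da,
    DifferenceEntropy = -sum(p_d[pd_nz] * log2(p_d[pd_nz])),
    DifferenceVariance = sum((k_d - da)^2 * p_d),
    Id = sum(p_d / (1 + k_d)),
    Idm = sum(p_d / (1 + k_d^2)),
    Idmn = sum(p_d / (1 + (k_d / ng)^2)),
    Idn = sum(p_d / (1 + k_d / ng)),
    Imc1 = imc1,
    Imc2 = imc2,
    InverseVariance = if (ng > 1) sum(p_d[-1] / k_d[-1]^2) else 0,
    JointAverage = mu,
    JointEnergy = sum(P^2),
    JointEntropy = hxy,
    MCC = mcc,
    MaximumProbability = max(P),
    SumAverage = sum(k_s * p_s),
    SumEntropy = -sum(p_s[ps_nz] * log2(p_s[ps_nz])),
    SumSquares = sig2)
}

#' Gray-level co-occurrence matrix features (24 features)
#'
#' One symmetric, normalized co-occurrence matrix per direction (the 13
#' unique distance-1 offsets of the 26-neighbourhood by default);
#' feature values are averaged over directions. Degenerate single-level
#' ROIs yield Correlation = MCC = 1 and zero entropies.
#'
#' @param droi a `discretized_roi` from [discretize()].
#' @param distances integer voxel distances (default 1).
#' @param symmetric logical; co-occurrences counted in both directions.
#' @return Named numeric vector of 24 features.
#' @export
glcm_features <- function(droi, distances = 1, symmetric = TRUE) {
  dirs <- unique_directions_13()
  offs <- do.call(rbind, lapply(distances, function(d) dirs * d))
  counts <- cpp_glcm_counts(droi$levels, droi$ng, offs)
  if (!symmetric) counts <- counts / 2  # same normalized matrix either way
  ndir <- dim(counts)[3]
  acc <- NULL
  used <- 0L
  for (k in seq_len(ndir)) {
    M <- counts[, , k, drop = FALSE]
    dim(M) <- dim(counts)[1:2]
    tot <- sum(M)
    if (tot == 0) next
    f <- glcm_single(M / tot, droi$ng)
    acc <- if (is.null(acc)) f else acc + f
    used <- used + 1L
  }
  if (used == 0L) stop("no valid co-occurrence pairs in ROI")
  acc / used
}

rlm_style_features <- function(P, np) {
  # Shared formula set for run-length (GLRLM) and size-zone (GLSZM)
  # matrices: P is ng x max-size counts, np the ROI voxel count.
  nr <- sum(P)
  i <- row(P); j <- col(P)
  p <- P / nr
  ri <- rowSums(P)
  rj <- colSums(P)
  mu_i <- sum(i * p)
  mu_j <- sum(j * p)
  nzp <- p > 0
  vals <- c(
    sum(rj / (1:ncol(P))^2) / nr,            # short emphasis
    sum(rj * (1:ncol(P))^2) / nr,            # long emphasis
    sum(ri^2) / nr,                          # gray-level non-uniformity
    sum(ri^2) / nr^2,                        # ... normalized
    sum(rj^2) / nr,                          # size non-uniformity
    sum(rj^2) / nr^2,                        # ... normalized
    nr / np,                                 # percentage
    sum((i - mu_i)^2 * p),                   # gray-level variance
    sum((j - mu_j)^2 * p),                   # size variance
    -sum(p[nzp] * log2(p[nzp])),             # entropy
    sum(ri / (1:nrow(P))^2) / nr,            # low gray-level
    sum(ri * (1:nrow(P))^2) / nr,            # high gray-level
    sum(P / (i^2 * j^2)) / nr,               # short+low
    sum(P * i^2 / j^2) / nr,                 # short+high
    sum(P * j^2 / i^2) / nr,                 # long+low
    sum(P * i^2 * j^2) / nr)                 # long+high
  vals
}

#' Gray-level run-length matrix features (16 features)
#'
#' Run-length matrices are built per direction over the 13 unique
#' distance-1 offsets and the features averaged across directions.
#'
#' @param droi a `discretized_roi`.
#' @param directions integer matrix of voxel offsets (default: the 13
#'   unique 26-neighbourhood directions).
#' @return Named numeric vector of 16 features.
#' @export
glrlm_features <- function(droi, directions = unique_directions_13()) {
  counts <- cpp_glrlm_counts(droi$levels, droi$ng, directions)
  ndir <- dim(counts)[3]
  acc <- NULL
  for (k in seq_len(ndir)) {
    P <- counts[, , k, drop = FALSE]
    dim(P) <- dim(counts)[1:2]
    v <- rlm_style_features(P, droi$n_voxels)
    acc <- if (is.null(acc)) v else acc + v
  }
  vals <- acc / ndir
  names(vals) <- c("ShortRunEmphasis", "LongRunEmphasis",
                   "GrayLevelNonUniformity",
                   "GrayLevelNonUniformityNormalized",
                   "RunLengthNonUniformity",
                   "RunLengthNonUniformityNormalized", "RunPercentage",
                   "GrayLevelVariance", "RunVariance", "RunEntropy",
                   "LowGrayLevelRunEmphasis", "HighGrayLevelRunEmphasis",
                   "ShortRunLowGrayLevelEmphasis",
                   "ShortRunHighGrayLevelEmphasis",
                   "LongRunLowGrayLevelEmphasis",
                   "LongRunHighGrayLevelEmphasis")
  vals[order(names(vals))]
}

#' Gray-level size-zone matrix features (16 features)
#'
#' A single matrix over 26-connected zones of equal gray level (no
#' directions).
#'
#' @param droi a `discretized_roi`.
#' @return Named numeric vector of 16 features.
#' @export
glszm_features <- function(droi) {
  zones <- cpp_glszm_zones(droi$levels)
  maxsz <- max(zones[, 2])
  P <- matrix(0, droi$ng, maxsz)
  for (r in seq_len(nrow(zones)))
    P[zones[r, 1], zones[r, 2]] <- P[zones[r, 1], zones[r, 2]] + 1
  vals <- rlm_style_features(P, droi$n_voxels)
  names(vals) <- c("SmallAreaEmphasis", "LargeAreaEmphasis",
                   "GrayLevelNonUniformity",
                   "GrayLevelNonUniformityNormalized",
                   "SizeZoneNonUniformity",
                   "SizeZoneNonUniformityNormalized", "ZonePercentage",
                   "GrayLevelVariance", "ZoneVariance", "ZoneEntropy",
                   "LowGrayLevelZoneEmphasis", "HighGrayLevelZoneEmphasis",
                   "SmallAreaLowGrayLevelEmphasis",
                   "SmallAreaHighGrayLevelEmphasis",
                   "LargeAreaLowGrayLevelEmphasis",
                   "LargeAreaHighGrayLevelEmphasis")
  vals[order(names(vals))]
}

#' Neighborhood gray-tone difference features (5 features)
#'
#' Neighbourhood averages use in-ROI 26-neighbours only; voxels with no
#' in-ROI neighbour are excluded. A constant ROI yields Contrast =
#' Complexity = 0; an all-uniform neighbourhood caps Coarseness at 1e6
#' instead of infinity.
#'
#' @param droi a `discretized_roi`.
#' @return Named numeric vector of 5 features.
#' @export
ngtdm_features <- function(droi) {
  M <- cpp_ngtdm(droi$levels, droi$ng)
  n_i <- M[, 1]
  s_i <- M[, 2]
  nvp <- sum(n_i)
  if (nvp == 0) stop("NGTDM: no voxel has an in-ROI neighbour")
  p_i <- n_i / nvp
  occ <- which(p_i > 0)
  ngp <- length(occ)
  lv <- seq_len(droi$ng)
  denom_coarse <- sum(p_i * s_i)
  coarse <- if (denom_coarse > 0) min(1 / denom_coarse, 1e6) else 1e6
  contrast <- 0
  busy <- 0
  complexity <- 0
  strength <- 0
  if (ngp > 1) {
    pm <- outer(p_i[occ], p_i[occ])
    dm <- outer(lv[occ], lv[occ], `-`)
    contrast <- sum(pm * dm^2) / (ngp * (ngp - 1)) * sum(s_i) / nvp
    ip <- lv[occ] * p_i[occ]
    denom_busy <- sum(abs(outer(ip, ip, `-`)))
    busy <- if (denom_busy > 0) denom_coarse / denom_busy else 0
    ps <- p_i[occ] * s_i[occ]
    complexity <- sum(abs(dm) * (outer(ps, rep(1, ngp)) +
                                   outer(rep(1, ngp), ps)) /
                        (outer(p_i[occ], p_i[occ], `+`))) / nvp
    ssum <- sum(s_i)
    strength <- if (ssum > 0)
      sum((outer(p_i[occ], p_i[occ], `+`)) * dm^2) / ssum else 0
  }
  c(Busyness = busy, Coarseness = coarse, Complexity = complexity,
    Contrast = contrast, Strength = strength)
}

#' Gray-level dependence matrix features (14 features)
#'
#' The dependence of a voxel is the number of its in-ROI 26-neighbours
#' whose gray level differs by at most `alpha`; the matrix rows are gray
#' levels and columns dependence sizes (count + 1).
#'
#' @param droi a `discretized_roi`.
#' @param alpha gray-level tolerance (default 0).
#' @return Named numeric vector of 14 features.
#' @export
gldm_features <- function(droi, alpha = 0) {
  M <- cpp_gldm_counts(droi$levels, droi$ng, as.integer(alpha))
  # columns are dependence counts 0..26 -> sizes j = count + 1
  P <- M
  nz <- sum(P)
  i <- row(P); j <- col(P)
  p <- P / nz
  ri <- rowSums(P)
  rj <- colSums(P)
  jj <- seq_len(ncol(P))
  ii <- seq_len(nrow(P))
  mu_i <- sum(i * p)
  mu_j <- sum(j * p)
  nzp <- p > 0
  c(DependenceEntropy = -sum(p[nzp] * log2(p[nzp])),
    DependenceNonUniformity = sum(rj^2) / nz,
    DependenceNonUniformityNormalized = sum(rj^2) / nz^2,
    DependenceVariance = sum((j - mu_j)^2 * p),
    GrayLevelNonUniformity = sum(ri^2) / nz,
    GrayLevelVariance = sum((i - mu_i)^2 * p),
    HighGrayLevelEmphasis = sum(ri * ii^2) / nz,
    LargeDependenceEmphasis = sum(rj * jj^2) / nz,
    LargeDependenceHighGrayLevelEmphasis = sum(P * i^2 * j^2) / nz,
    LargeDependenceLowGrayLevelEmphasis = sum(P * j^2 / i^2) / nz,
    LowGrayLevelEmphasis = sum(ri / ii^2) / nz,
    SmallDependenceEmphasis = sum(rj / jj^2) / nz,
    SmallDependenceHighGrayLevelEmphasis = sum(P * i^2 / j^2) / nz,
    SmallDependenceLowGrayLevelEmphasis = sum(P / (i^2 * j^2)) / nz)
}
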