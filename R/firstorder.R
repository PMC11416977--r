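#' First-order intensity statistics (18 features)
#'
#' Standard first-order radiomic features over the ROI intensity
#' distribution. `Entropy` and `Uniformity` are computed on the
#' fixed-bin-width discretized histogram; all moments use the population
#' (1/N) convention; `Kurtosis` is the uncorrected fourth standardized
#' moment (3 for a normal distribution). Dispersion features of a
#' constant or single-voxel ROI are 0 by convention, never `NaN`.
#'
#' @param volume an `image_volume` or 3D array.
#' @param mask aligned `roi_mask`, non-empty.
#' @param bin_width HU bin width for the histogram-based features.
#' @param spacing voxel spacing in mm (taken from `volume` when it is an
#'   `image_volume`); used by `TotalEnergy`.
#' @return Named numeric vector of 18 features.
#' @export
firstorder_features <- function(volume, mask, bin_width = 25,
                                spacing = NULL) {
  vox <- if (inherits(volume, "image_volume")) volume$voxels else volume
  if (is.null(spacing))
    spacing <- if (inherits(volume, "image_volume")) volume$spacing else c(1, 1, 1)
  x <- vox[mask$voxels == 1L]
  if (length(x) == 0L) stop("empty ROI: mask has no foreground voxels")
  if (any(!is.finite(x))) stop("non-finite voxel values inside the ROI")
  n <- length(x)
  mu <- mean(x)
  v <- sum((x - mu)^2) / n
  s <- sqrt(v)
  p10 <- unname(quantile(x, 0.10, type = 7))
  p90 <- unname(quantile(x, 0.90, type = 7))
  robust <- x[x >= p10 & x <= p90]
  lev <- floor((x - min(x)) / bin_width)
  p <- tabulate(lev + 1L) / n
  p <- p[p > 0]
  c("10Percentile" = p10,
    "90Percentile" = p90,
    Energy = sum(x^2),
    Entropy = -sum(p * log2(p)),
    InterquartileRange = unname(quantile(x, 0.75, type = 7) -
                                  quantile(x, 0.25, type = 7)),
    Kurtosis = if (v > 0) sum((x - mu)^4) / n / v^2 else 0,
    Maximum = max(x),
    MeanAbsoluteDeviation = mean(abs(x - mu)),
    Mean = mu,
    Median = unname(quantile(x, 0.5, type = 7)),
    Minimum = min(x),
    Range = max(x) - min(x),
    RobustMeanAbsoluteDeviation = mean(abs(robust - mean(robust))),
    RootMeanSquared = sqrt(mean(x^2)),
    Skewness = if (v > 0) sum((x - mu)^3) / n / s^3 else 0,
    TotalEnergy = sum(x^2) * prod(spacing),
    Uniformity = sum(p^2),
    Variance = v)
}
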