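FAMILY_FEATURES <- list(
  firstorder = c("10Percentile", "90Percentile", "Energy", "Entropy",
                 "InterquartileRange", "Kurtosis", "Maximum",
                 "MeanAbsoluteDeviation", "Mean", "Median", "Minimum",
                 "Range", "RobustMeanAbsoluteDeviation", "RootMeanSquared",
                 "Skewness", "TotalEnergy", "Uniformity", "Variance"),
  shape = c("Elongation", "Flatness", "LeastAxisLength", "MajorAxisLength",
            "Maximum2DDiameterColumn", "Maximum2DDiameterRow",
            "Maximum2DDiameterSlice", "Maximum3DDiameter", "MeshVolume",
            "MinorAxisLength", "Sphericity", "SurfaceArea",
            "SurfaceVolumeRatio", "VoxelVolume"),
  glcm = c("Autocorrelation", "ClusterProminence", "ClusterShade",
           "ClusterTendency", "Contrast", "Correlation",
           "DifferenceAverage", "DifferenceEntropy", "DifferenceVariance",
           "Id", "Idm", "Idmn", "Idn", "Imc1", "Imc2", "InverseVariance",
           "JointAverage", "JointEnergy", "JointEntropy", "MCC",
           "MaximumProbability", "SumAverage", "SumEntropy", "SumSquares"),
  glrlm = c("GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
            "GrayLevelVariance", "HighGrayLevelRunEmphasis",
            "LongRunEmphasis", "LongRunHighGrayLevelEmphasis",
            "LongRunLowGrayLevelEmphasis", "LowGrayLevelRunEmphasis",
            "RunEntropy", "RunLengthNonUniformity",
            "RunLengthNonUniformityNormalized", "RunPercentage",
            "RunVariance", "ShortRunEmphasis",
            "ShortRunHighGrayLevelEmphasis", "ShortRunLowGrayLevelEmphasis"),
  glszm = c("GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
            "GrayLevelVariance", "HighGrayLevelZoneEmphasis",
            "LargeAreaEmphasis", "LargeAreaHighGrayLevelEmphasis",
            "LargeAreaLowGrayLevelEmphasis", "LowGrayLevelZoneEmphasis",
            "SizeZoneNonUniformity", "SizeZoneNonUniformityNormalized",
            "SmallAreaEmphasis", "SmallAreaHighGrayLevelEmphasis",
            "SmallAreaLowGrayLevelEmphasis", "ZoneEntropy",
            "ZonePercentage", "ZoneVariance"),
  ngtdm = c("Busyness", "Coarseness", "Complexity", "Contrast", "Strength"),
  gldm = c("DependenceEntropy", "DependenceNonUniformity",
           "DependenceNonUniformityNormalized", "DependenceVariance",
           "GrayLevelNonUniformity", "GrayLevelVariance",
           "HighGrayLevelEmphasis", "LargeDependenceEmphasis",
           "LargeDependenceHighGrayLevelEmphasis",
           "LargeDependenceLowGrayLevelEmphasis", "LowGrayLevelEmphasis",
           "SmallDependenceEmphasis", "SmallDependenceHighGrayLevelEmphasis",
           "SmallDependenceLowGrayLevelEmphasis"))

WAVELET_KEYS <- c("LLL", "LLH", "LHL", "LHH", "HLL", "HLH", "HHL", "HHH")

#' Extraction configuration
#'
#' @param bin_width HU bin width for intensity discretization.
#' @param wavelet analysis wavelet for the filter bank
#'   (`"coif1"` or `"haar"`).
#' @param alpha gray-level tolerance of the dependence (GLDM) family.
#' @param images character vector of image types: `"original"` and/or
#'   `"wavelet-XXX"` keys; the default is all nine.
#' @param families feature families to compute; `shape` is only ever
#'   computed on the original image.
#' @return An `extract_config` list.
#' @export
extract_config <- function(bin_width = 25, wavelet = "coif1", alpha = 0,
                           images = c("original",
                                      paste0("wavelet-", WAVELET_KEYS)),
                           families = names(FAMILY_FEATURES)) {
  stopifnot(all(families %in% names(FAMILY_FEATURES)))
  bad <- setdiff(images, c("original", paste0("wavelet-", WAVELET_KEYS)))
  if (length(bad)) stop("unknown image types: ", paste(bad, collapse = ", "))
  structure(list(bin_width = bin_width, wavelet = wavelet, alpha = alpha,
                 images = images, families = families),
            class = "extract_config")
}

#' Canonical feature manifest
#'
#' The ordered feature identifiers `<image>_<family>_<name>` produced by
#' [extract_all()] under a configuration. The default configuration
#' (original + 8 wavelet sub-bands, 7 families) yields exactly 851 ids:
#' 162 first-order, 14 shape, 216 GLCM, 144 GLRLM, 144 GLSZM, 45 NGTDM
#' and 126 GLDM features.
#'
#' @param config an [extract_config()].
#' @return Character vector of feature ids in canonical order.
#' @export
feature_manifest <- function(config = extract_config()) {
  ids <- character(0)
  fams <- intersect(names(FAMILY_FEATURES), config$families)
  for (img in config$images) {
    for (fam in fams) {
      if (fam == "shape" && img != "original") next
      ids <- c(ids, paste(img, fam, FAMILY_FEATURES[[fam]], sep = "_"))
    }
  }
  ids
}

extract_one_image <- function(vox, mask, spacing, families, bin_width,
                              alpha) {
  out <- list()
  if ("firstorder" %in% families)
    out$firstorder <- firstorder_features(vox, mask, bin_width = bin_width,
                                          spacing = spacing)
  need_droi <- any(c("glcm", "glrlm", "glszm", "ngtdm", "gldm") %in% families)
  if (need_droi) {
    droi <- discretize(vox, mask, bin_width = bin_width)
    if ("glcm" %in% families) out$glcm <- glcm_features(droi)
    if ("glrlm" %in% families) out$glrlm <- glrlm_features(droi)
    if ("glszm" %in% families) out$glszm <- glszm_features(droi)
    if ("ngtdm" %in% families) out$ngtdm <- ngtdm_features(droi)
    if ("gldm" %in% families) out$gldm <- gldm_features(droi, alpha = alpha)
  }
  out
}

#' Extract the full radiomic feature vector for one case
#'
#' Applies the wavelet filter bank, discretizes each image over the ROI,
#' and computes the configured feature families. With the default
#' configuration the result has exactly 851 entries named
#' `<image>_<family>_<name>` in the canonical manifest order.
#'
#' @param volume an `image_volume`.
#' @param mask the aligned `roi_mask`.
#' @param config an [extract_config()].
#' @return Named numeric vector; an error names the first feature id
#'   that evaluated to a non-finite value.
#' @export
extract_all <- function(volume, mask, config = extract_config()) {
  cropped <- crop_to_roi(volume, mask, margin_voxels = 4)
  vol <- cropped$volume
  msk <- cropped$mask
  fams <- intersect(names(FAMILY_FEATURES), config$families)
  res <- list()
  if ("original" %in% config$images) {
    per <- extract_one_image(vol$voxels, msk, vol$spacing,
                             setdiff(fams, "shape"), config$bin_width,
                             config$alpha)
    if ("shape" %in% fams)
      per$shape <- shape_features(msk, spacing = vol$spacing)
    res$original <- per
  }
  wav_imgs <- grep("^wavelet-", config$images, value = TRUE)
  if (length(wav_imgs)) {
    bank <- wavelet_decompose(vol$voxels, wavelet = config$wavelet)
    for (img in wav_imgs) {
      key <- sub("^wavelet-", "", img)
      res[[img]] <- extract_one_image(bank[[key]], msk, vol$spacing,
                                      setdiff(fams, "shape"),
                                      config$bin_width, config$alpha)
    }
  }
  flat <- unlist(lapply(config$images, function(img) {
    unlist(lapply(fams, function(fam) {
      v <- res[[img]][[fam]]
      if (is.null(v)) return(NULL)
      setNames(v, paste(img, fam, names(v), sep = "_"))
    }))
  }))
  manifest <- feature_manifest(config)
  flat <- flat[manifest]
  names(flat) <- manifest
  bad <- !is.finite(flat)
  if (any(bad))
    stop("non-finite feature value(s): ",
         paste(head(manifest[bad], 5), collapse = ", "))
  flat
}

#' Extract features for every case of a cohort
#'
#' @param volumes list of `image_volume`s.
#' @param masks list of aligned `roi_mask`s.
#' @param config an [extract_config()].
#' @param case_ids optional row names.
#' @return Numeric matrix, cases x features, columns in manifest order.
#' @export
extract_cohort <- function(volumes, masks, config = extract_config(),
                           case_ids = NULL) {
  stopifnot(length(volumes) == length(masks))
  rows <- lapply(seq_along(volumes), function(i)
    extract_all(volumes[[i]], masks[[i]], config))
  mat <- do.call(rbind, rows)
  rownames(mat) <- if (is.null(case_ids))
    sprintf("case_%03d", seq_along(volumes)) else case_ids
  mat
}
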