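#' Discretize ROI intensities into gray levels
#'
#' Fixed-bin-width quantization anchored at the ROI minimum:
#' `level(v) = floor((HU(v) - min) / bin_width) + 1`. This keeps the
#' number of occupied levels data-adaptive and makes every texture
#' feature invariant to a constant HU shift.
#'
#' @param volume an `image_volume` (or a bare 3D array, e.g. a wavelet
#'   sub-band).
#' @param mask the aligned `roi_mask`, non-empty.
#' @param bin_width bin width in HU (> 0); default 25.
#' @return A `discretized_roi` with `levels` (integer array, `NA`
#'   outside the ROI), `ng` (highest occupied level), `n_voxels`,
#'   `bin_width`.
#' @export
discretize <- function(volume, mask, bin_width = 25) {
  if (bin_width <= 0) stop("bin_width must be positive")
  vox <- if (inherits(volume, "image_volume")) volume$voxels else volume
  if (!identical(dim(vox), dim(mask$voxels)))
    stop("mask grid does not align with volume grid")
  inside <- mask$voxels == 1L
  if (!any(inside)) stop("empty ROI: mask has no foreground voxels")
  vals <- vox[inside]
  if (any(!is.finite(vals)))
    stop("non-finite voxel values inside the ROI")
  lev <- array(NA_integer_, dim = dim(vox))
  lev[inside] <- as.integer(floor((vals - min(vals)) / bin_width)) + 1L
  structure(list(levels = lev, ng = max(lev, na.rm = TRUE),
                 n_voxels = sum(inside), bin_width = bin_width),
            class = "discretized_roi")
}

# The 13 unique distance-1 offsets of the 26-neighbourhood (one per
# antipodal pair), in (x, y, z) voxel steps.
unique_directions_13 <- function() {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  keep <- g[, 3] > 0 | (g[, 3] == 0 & g[, 2] > 0) |
    (g[, 3] == 0 & g[, 2] == 0 & g[, 1] > 0)
  unname(g[keep, , drop = FALSE])
}
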