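#' Construct an image volume
#'
#' A 3D scalar grid of CT attenuation values in Hounsfield units (HU)
#' together with its physical voxel spacing.
#'
#' @param voxels 3D numeric array of HU values.
#' @param spacing numeric length-3, voxel spacing in mm per axis
#'   (strictly positive).
#' @param origin numeric length-3, physical offset in mm.
#' @return An object of class `image_volume` with fields `voxels`,
#'   `spacing`, `origin`.
#' @export
image_volume <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (length(dim(voxels)) != 3L)
    stop("`voxels` must be a 3D array")
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three strictly positive values (mm)")
  if (any(!is.finite(voxels)))
    stop("volume contains non-finite voxel values")
  structure(list(voxels = voxels, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "image_volume")
}

#' Construct a binary region-of-interest mask
#'
#' Any non-zero voxel is treated as foreground.
#'
#' @param voxels 3D array; non-zero entries mark the tumor ROI.
#' @param spacing voxel spacing in mm, matching the associated volume.
#' @return An object of class `roi_mask`.
#' @export
roi_mask <- function(voxels, spacing = c(1, 1, 1)) {
  if (length(dim(voxels)) != 3L)
    stop("mask `voxels` must be a 3D array")
  vox <- array(as.integer(voxels != 0), dim = dim(voxels))
  structure(list(voxels = vox, spacing = as.numeric(spacing)),
            class = "roi_mask")
}

#' @export
print.image_volume <- function(x, ...) {
  cat("<image_volume> ", paste(dim(x$voxels), collapse = "x"),
      " voxels, spacing ", paste(signif(x$spacing, 3), collapse = "x"),
      " mm, HU range [", round(min(x$voxels)), ", ", round(max(x$voxels)),
      "]\n", sep = "")
  invisible(x)
}

#' @export
print.roi_mask <- function(x, ...) {
  cat("<roi_mask> ", paste(dim(x$voxels), collapse = "x"),
      " voxels, ", sum(x$voxels), " foreground\n", sep = "")
  invisible(x)
}

#' Write a volume or mask to NIfTI
#'
#' @param x an `image_volume` or `roi_mask`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path) {
  img <- RNifti::asNifti(x$voxels)
  RNifti::pixdim(img) <- x$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a volume from NIfTI
#'
#' @param path a `.nii`/`.nii.gz` file.
#' @return An `image_volume`; spacing taken from the NIfTI pixdim.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  image_volume(array(as.numeric(img), dim = dim(img)),
               spacing = RNifti::pixdim(img)[1:3])
}

#' Read an ROI mask from NIfTI, aligned to a volume
#'
#' Non-zero labels are binarized to 1. The grid shape must match the
#' volume exactly.
#'
#' @param path a `.nii`/`.nii.gz` file.
#' @param volume the `image_volume` the mask annotates.
#' @return An `roi_mask`.
#' @export
read_mask <- function(path, volume) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  if (!identical(dim(img), dim(volume$voxels)))
    stop("mask grid ", paste(dim(img), collapse = "x"),
         " does not align with volume grid ",
         paste(dim(volume$voxels), collapse = "x"))
  roi_mask(array(as.numeric(img), dim = dim(img)), spacing = volume$spacing)
}

#' Apply a CT display window
#'
#' Clips voxel values to `[level - width/2, level + width/2]`. The
#' conventional mediastinal segmentation window used here is level 50 HU,
#' width 2000 HU, i.e. clip bounds \[-950, 1050\] HU. Windowing is not part
#' of the default feature-extraction path; it is exposed for parity with
#' the segmentation display settings.
#'
#' @param volume an `image_volume`.
#' @param level window level in HU.
#' @param width window width in HU (> 0).
#' @return An `image_volume` with clipped voxels; metadata unchanged.
#' @export
apply_window <- function(volume, level = 50, width = 2000) {
  if (width <= 0) stop("window width must be positive")
  lo <- level - width / 2
  hi <- level + width / 2
  v <- volume$voxels
  v[v < lo] <- lo
  v[v > hi] <- hi
  image_volume(v, spacing = volume$spacing, origin = volume$origin)
}

#' Crop a volume and mask to the ROI bounding box
#'
#' @param volume an `image_volume`.
#' @param mask the aligned `roi_mask` (non-empty).
#' @param margin_voxels margin added on each side, clipped at the grid
#'   border.
#' @return list with cropped `volume` and `mask`; the foreground voxel
#'   count is preserved.
#' @export
crop_to_roi <- function(volume, mask, margin_voxels = 0) {
  if (!identical(dim(volume$voxels), dim(mask$voxels)))
    stop("mask grid does not align with volume grid")
  idx <- which(mask$voxels == 1L, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("empty ROI: mask has no foreground voxels")
  d <- dim(mask$voxels)
  lo <- pmax(apply(idx, 2, min) - margin_voxels, 1L)
  hi <- pmin(apply(idx, 2, max) + margin_voxels, d)
  v <- volume$voxels[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  m <- mask$voxels[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  list(volume = image_volume(v, spacing = volume$spacing,
                             origin = volume$origin + (lo - 1) * volume$spacing),
       mask = roi_mask(m, spacing = mask$spacing))
}
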