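#' Specify a textured CT phantom
#'
#' Describes a synthetic tumor phantom: an ellipsoidal ROI carrying a
#' correlated Gaussian random-field texture, embedded in lung-like noisy
#' background. The texture is smoothed white noise (Gaussian kernel with
#' width equal to the correlation length), the simplest stationary field
#' with a tunable second-order structure.
#'
#' @param grid_shape voxels per axis (all >= 8).
#' @param voxel_spacing mm per axis.
#' @param roi_axes ellipsoid semi-axes in mm; must fit inside the grid.
#' @param texture_correlation_length Gaussian kernel width in mm
#'   (0 = white noise).
#' @param texture_contrast standard deviation of the ROI texture in HU
#'   (>= 0; 0 gives a spatially constant interior).
#' @param roi_mean mean HU inside the ROI (soft-tissue tumor default).
#' @param background_mean,background_std HU mean/sd of the background.
#' @param seed integer; identical seeds give bit-identical phantoms.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(grid_shape = c(32, 32, 32),
                         voxel_spacing = c(1, 1, 1),
                         roi_axes = c(10, 10, 10),
                         texture_correlation_length = 2,
                         texture_contrast = 40,
                         roi_mean = 40,
                         background_mean = -800,
                         background_std = 30,
                         seed = 1L) {
  if (any(grid_shape < 8)) stop("grid_shape must be >= 8 on every axis")
  if (texture_contrast < 0) stop("texture_contrast must be >= 0")
  if (any(voxel_spacing <= 0)) stop("voxel_spacing must be positive")
  half_extent <- (grid_shape - 2) / 2 * voxel_spacing
  if (any(roi_axes >= half_extent))
    stop("ROI semi-axes (", paste(roi_axes, collapse = ", "),
         " mm) do not fit inside the grid (half extent ",
         paste(signif(half_extent, 4), collapse = ", "), " mm)")
  structure(list(grid_shape = as.integer(grid_shape),
                 voxel_spacing = as.numeric(voxel_spacing),
                 roi_axes = as.numeric(roi_axes),
                 texture_correlation_length = texture_correlation_length,
                 texture_contrast = texture_contrast,
                 roi_mean = roi_mean,
                 background_mean = background_mean,
                 background_std = background_std,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Gaussian kernel with sd `sigma` (in voxels), truncated at 3 sigma.
gauss_kernel <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(3 * sigma))
  k <- dnorm(seq(-r, r), sd = sigma)
  k / sum(k)
}

# Unit-variance correlated Gaussian field: white noise smoothed per axis,
# rescaled by the exact l2 norm of the separable kernel.
correlated_field <- function(dims, corr_len, spacing) {
  f <- array(rnorm(prod(dims)), dim = dims)
  norm <- 1
  for (a in 1:3) {
    k <- gauss_kernel(corr_len / spacing[a])
    if (length(k) > 1) {
      f <- cpp_conv_axis(f, k, a)
      norm <- norm * sqrt(sum(k^2))
    }
  }
  f / norm
}

#' Generate a textured phantom volume and mask
#'
#' Deterministic in `spec$seed`: the same spec yields voxelwise-identical
#' output. Inside the ellipsoid the voxels are
#' `roi_mean + texture_contrast * G` where `G` is a unit-variance
#' correlated Gaussian field; outside they are independent background
#' noise.
#'
#' @param spec a [phantom_spec()].
#' @return list with `volume` (an `image_volume`) and `mask`
#'   (an `roi_mask`).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$grid_shape
  sp <- spec$voxel_spacing
  centre <- (d - 1) / 2
  cx <- (seq_len(d[1]) - 1 - centre[1]) * sp[1]
  cy <- (seq_len(d[2]) - 1 - centre[2]) * sp[2]
  cz <- (seq_len(d[3]) - 1 - centre[3]) * sp[3]
  q <- outer(outer((cx / spec$roi_axes[1])^2,
                   (cy / spec$roi_axes[2])^2, `+`),
             (cz / spec$roi_axes[3])^2, `+`)
  mask <- array(as.integer(q <= 1), dim = d)
  if (sum(mask) < 1) stop("ROI ellipsoid contains no voxels")
  vol <- with_seed(spec$seed, {
    bg <- array(rnorm(prod(d), spec$background_mean, spec$background_std),
                dim = d)
    tex <- spec$roi_mean + spec$texture_contrast *
      correlated_field(d, spec$texture_correlation_length, sp)
    bg[mask == 1L] <- tex[mask == 1L]
    bg
  })
  list(volume = image_volume(vol, spacing = sp),
       mask = roi_mask(mask, spacing = sp))
}
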