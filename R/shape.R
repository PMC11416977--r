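#' Morphological (shape) features (14 features)
#'
#' Computed from a closed triangulated surface of the binary mask
#' (marching tetrahedra on the mask padded by one background layer, with
#' vertices at edge midpoints), plus the principal-component axis
#' lengths of the physical voxel-centre coordinates. All lengths are in
#' mm, areas in mm^2, volumes in mm^3.
#'
#' `Maximum2DDiameterSlice` drops the third (slice) axis,
#' `Maximum2DDiameterColumn` the first, and `Maximum2DDiameterRow` the
#' second. A single-voxel mask has axis lengths 0 and
#' Elongation = Flatness = 1 by convention.
#'
#' @param mask an `roi_mask`, non-empty.
#' @param spacing voxel spacing in mm (defaults to the mask's).
#' @return Named numeric vector of 14 features.
#' @export
shape_features <- function(mask, spacing = NULL) {
  if (is.null(spacing)) spacing <- mask$spacing
  m <- mask$voxels
  n_fg <- sum(m)
  if (n_fg == 0L) stop("empty ROI: mask has no foreground voxels")
  d <- dim(m)
  pad <- 4L
  padded <- array(0, dim = d + 2L * pad)
  padded[pad + seq_len(d[1]), pad + seq_len(d[2]), pad + seq_len(d[3])] <- m
  # anti-aliased meshing: smooth the binary indicator (sigma = 1 voxel)
  # and triangulate the 0.5 level set with edge interpolation; for very
  # small masks where the smoothed field stays below the level, fall
  # back to meshing the binary indicator directly.
  smoothed <- padded
  k <- gauss_kernel(1)
  for (ax in 1:3) smoothed <- cpp_conv_axis(smoothed, k, ax)
  mesh <- cpp_mesh_field(smoothed, as.numeric(spacing), 0.5)
  if (mesh$volume <= 0 || mesh$area <= 0)
    mesh <- cpp_mesh_field(padded, as.numeric(spacing), 0.5)
  verts <- unique(mesh$vertices)
  diam <- cpp_max_diameters(verts)
  idx <- which(m == 1L, arr.ind = TRUE)
  coords <- sweep(idx - 1, 2, spacing, `*`)
  if (n_fg > 1) {
    ev <- sort(pmax(eigen(stats::cov(coords), symmetric = TRUE,
                          only.values = TRUE)$values, 0),
               decreasing = TRUE)
  } else ev <- c(0, 0, 0)
  axes <- 4 * sqrt(ev)
  elong <- if (ev[1] > 0) sqrt(ev[2] / ev[1]) else 1
  flat <- if (ev[1] > 0) sqrt(ev[3] / ev[1]) else 1
  vol <- mesh$volume
  area <- mesh$area
  c(Elongation = elong,
    Flatness = flat,
    LeastAxisLength = axes[3],
    MajorAxisLength = axes[1],
    Maximum2DDiameterColumn = diam[2],
    Maximum2DDiameterRow = diam[3],
    Maximum2DDiameterSlice = diam[4],
    Maximum3DDiameter = diam[1],
    MeshVolume = vol,
    MinorAxisLength = axes[2],
    Sphericity = if (area > 0) (36 * pi * vol^2)^(1 / 3) / area else 1,
    SurfaceArea = area,
    SurfaceVolumeRatio = if (vol > 0) area / vol else 0,
    VoxelVolume = n_fg * prod(spacing))
}
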