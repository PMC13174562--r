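# Separable Gaussian filtering and the two preprocessing filters used by
# the 3-D pipeline: ellipsoidal white top-hat (septin channel) and Gaussian
# high-pass (microtubule channel).

# sampled Gaussian kernel; order 0, 1 or 2 gives G, G' or G''
.gauss_kernel <- function(sigma_px, order = 0L) {
  if (sigma_px <= 0) stop("sigma must be positive")
  r <- max(1L, as.integer(ceiling(4 * sigma_px)))
  x <- (-r):r
  g <- exp(-x^2 / (2 * sigma_px^2))
  g <- g / sum(g)
  if (order == 0L) return(g)
  if (order == 1L) return(-x / sigma_px^2 * g)
  if (order == 2L) return((x^2 - sigma_px^2) / sigma_px^4 * g)
  stop("order must be 0, 1 or 2")
}

# separable filtering with per-axis sigma in *voxels*; order per axis
.gauss_sep <- function(vol, sigma_px, orders = c(0L, 0L, 0L)) {
  d <- dim(vol)
  out <- as.numeric(vol)
  for (ax in 1:3) {
    if (d[ax] == 1L) next
    k <- .gauss_kernel(sigma_px[ax], orders[ax])
    out <- .conv1d_axis(out, d, k, ax)
  }
  array(out, d)
}

#' Gaussian smoothing with physically scaled anisotropy
#'
#' Separable Gaussian filter whose lateral sigma is given in nm and whose
#' axial sigma is the same physical value (i.e., the axial sigma in voxels
#' is divided by the z/xy ratio), so smoothing is isotropic in physical
#' space. Mirror boundary conditions.
#'
#' @param x `channel_stack`, matrix or 3-D array.
#' @param sigma_nm Gaussian sigma in nm (one physical scale).
#' @param geometry Voxel geometry when `x` is a bare array.
#' @return Array of the same shape.
#' @export
gaussian_smooth <- function(x, sigma_nm, geometry = NULL) {
  g <- .geom(x, geometry)
  v <- .values(x)
  sig <- c(sigma_nm / g$dx, sigma_nm / g$dy, sigma_nm / g$dz)
  .gauss_sep(v, sig)
}

#' Gaussian high-pass filter
#'
#' Subtracts a Gaussian-blurred copy from the image, suppressing smooth
#' large-scale intensity (e.g., centrosomal flare) while preserving
#' filament cores. The output may be negative; downstream segmentation
#' clamps at zero.
#'
#' @inheritParams gaussian_smooth
#' @return Array of the same shape (may contain negative values).
#' @export
gaussian_highpass <- function(x, sigma_nm, geometry = NULL) {
  v <- .values(x)
  v - gaussian_smooth(x, sigma_nm, geometry)
}

# offsets (voxels) of an ellipsoid with physical radii (nm); always
# includes the center voxel so the element is never empty
.ellipsoid_offsets <- function(radii_xy_nm, radii_z_nm, geometry) {
  rx <- as.integer(floor(radii_xy_nm / geometry$dx + 1e-9))
  ry <- as.integer(floor(radii_xy_nm / geometry$dy + 1e-9))
  rz <- as.integer(floor(radii_z_nm / geometry$dz + 1e-9))
  off <- expand.grid(x = -rx:rx, y = -ry:ry, z = -rz:rz)
  keep <- (off$x * geometry$dx / radii_xy_nm)^2 +
    (off$y * geometry$dy / radii_xy_nm)^2 +
    (off$z * geometry$dz / radii_z_nm)^2 <= 1 + 1e-9
  m <- as.matrix(off[keep, , drop = FALSE])
  if (nrow(m) == 0) m <- matrix(0L, 1, 3)
  storage.mode(m) <- "integer"
  m
}

#' Ellipsoidal white top-hat (3-D background subtraction)
#'
#' Grey-value opening with an ellipsoidal structuring element whose axes
#' honor the voxel anisotropy, subtracted from the input. Structures
#' smaller than the element survive; smooth background is removed. Output
#' is non-negative and voxelwise no larger than the input.
#'
#' @param x `channel_stack`, matrix or 3-D array.
#' @param radii_xy_nm Lateral semi-axis of the structuring element (nm).
#' @param radii_z_nm Axial semi-axis (nm); defaults to the lateral value
#'   (same physical extent).
#' @param geometry Voxel geometry when `x` is a bare array.
#' @return Array of the same shape.
#' @export
white_tophat_3d <- function(x, radii_xy_nm = 500, radii_z_nm = radii_xy_nm,
                            geometry = NULL) {
  g <- .geom(x, geometry)
  v <- .values(x)
  if (radii_xy_nm <= 0 || radii_z_nm <= 0) stop("radii must be positive")
  off <- .ellipsoid_offsets(radii_xy_nm, radii_z_nm, g)
  d <- dim(v)
  if (2 * max(abs(off[, 1])) + 1 > d[1] || 2 * max(abs(off[, 2])) + 1 > d[2])
    stop("structuring element larger than the grid")
  er <- .morph_grey(as.numeric(v), d, off, FALSE)
  op <- .morph_grey(er, d, off, TRUE)
  out <- as.numeric(v) - op
  out[out < 0] <- 0  # numerical guard; opening <= input by construction
  array(out, d)
}
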