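#' Voxel geometry of an image stack
#'
#' Physical voxel spacing of a 2-D or 3-D acquisition. Lateral pixels are
#' assumed square (`dx == dy`); the axial/lateral ratio `z_xy_ratio` is what
#' every anisotropic operation in the package uses to scale its axial extent
#' so that physical distances are preserved.
#'
#' @param dx,dy Lateral voxel size in nm (must be equal).
#' @param dz Axial voxel size in nm. For 2-D images use the default
#'   `dz = dx` (the axial dimension is degenerate).
#' @return An object of class `voxel_geometry` with fields `dx`, `dy`, `dz`
#'   (nm) and `z_xy_ratio = dz/dx`.
#' @examples
#' geom <- voxel_geometry(108, 108, 200)
#' geom$z_xy_ratio
#' @export
voxel_geometry <- function(dx = 108, dy = dx, dz = dx) {
  stopifnot(is.numeric(dx), is.numeric(dy), is.numeric(dz),
            length(dx) == 1, length(dy) == 1, length(dz) == 1)
  if (!(dx > 0 && dy > 0 && dz > 0))
    stop("voxel sizes must be positive")
  if (abs(dx - dy) > 1e-9 * dx)
    stop("square lateral pixels are assumed (dx must equal dy)")
  structure(list(dx = dx, dy = dy, dz = dz, z_xy_ratio = dz / dx),
            class = "voxel_geometry")
}

#' @export
print.voxel_geometry <- function(x, ...) {
  cat(sprintf("voxel geometry: %.1f x %.1f x %.1f nm (z/xy = %.3f)\n",
              x$dx, x$dy, x$dz, x$z_xy_ratio))
  invisible(x)
}

# spacing vector (nm per voxel step) along x, y, z for a given array
.spacing <- function(geometry) c(geometry$dx, geometry$dy, geometry$dz)

# coerce 2-D matrix to single-slice 3-D array; returns list(values, dim2d)
.as_vol <- function(x) {
  d <- dim(x)
  if (is.null(d) || length(d) < 2 || length(d) > 3)
    stop("expected a 2-D matrix or 3-D array")
  if (length(d) == 2) x <- array(x, c(d, 1L))
  x
}

.check_finite_nonneg <- function(x, what = "intensities") {
  if (!all(is.finite(x))) stop(what, " must be finite")
  if (any(x < 0)) stop(what, " must be non-negative")
  invisible(TRUE)
}
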