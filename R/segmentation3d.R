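# Cell / nucleus / cytoplasm (exNuc) segmentation of a two-channel stack.

#' Masking parameters
#'
#' @param smooth_sigma_xy_nm Gaussian sigma (nm) for the cell-mask
#'   smoothing of the channel sum; the axial sigma is the same physical
#'   value. Default 500 nm.
#' @param min_cell_volume_um3 Minimum connected-component volume retained
#'   as cell (default 50 um^3; rejects debris).
#' @param closing_radii_xy_nm,closing_radii_z_nm Ellipsoidal closing radii
#'   (nm); axial default matches the lateral physical extent.
#' @param nuc_smooth_sigma_nm Sigma (nm) for the nucleus score smoothing
#'   (the nucleus is a coarse structure; default 1000 nm).
#' @param mt_median_fraction Candidate nuclei are retained only when their
#'   median raw MT is strictly below this fraction of the cell-wide MT
#'   median (default 0.5).
#' @return Object of class `masking_params`.
#' @export
masking_params <- function(smooth_sigma_xy_nm = 500,
                           min_cell_volume_um3 = 50,
                           closing_radii_xy_nm = 650,
                           closing_radii_z_nm = closing_radii_xy_nm,
                           nuc_smooth_sigma_nm = 1000,
                           mt_median_fraction = 0.5) {
  stopifnot(smooth_sigma_xy_nm > 0, min_cell_volume_um3 > 0,
            closing_radii_xy_nm > 0, closing_radii_z_nm > 0,
            nuc_smooth_sigma_nm > 0,
            mt_median_fraction > 0, mt_median_fraction <= 1)
  structure(as.list(environment()), class = "masking_params")
}

#' Cell mask from a two-channel stack
#'
#' Triangle-thresholds the Gaussian-smoothed sum of the two channels
#' (axial sigma scaled by the z/xy ratio), applies a 3-D ellipsoidal
#' closing honoring voxel anisotropy, and drops connected components
#' smaller than `min_cell_volume_um3`.
#'
#' @param pair A [field_pair()].
#' @param params A [masking_params()].
#' @return Logical array; attribute `empty_warning = TRUE` (plus an R
#'   warning) when no component survives.
#' @export
compute_cell_mask <- function(pair, params = masking_params()) {
  stopifnot(inherits(pair, "field_pair"))
  g <- pair$sep$geometry
  s <- gaussian_smooth(pair$sep$values + pair$mt$values,
                       params$smooth_sigma_xy_nm, g)
  thr <- triangle_threshold(as.numeric(s))
  mask <- s > thr
  if (any(mask))
    mask <- binary_close(mask, params$closing_radii_xy_nm, g,
                         params$closing_radii_z_nm)
  voxel_um3 <- g$dx * g$dy * g$dz / 1e9
  min_vox <- ceiling(params$min_cell_volume_um3 / voxel_um3)
  mask <- remove_small_components(mask, min_vox)
  if (!any(mask)) {
    warning("cell mask is empty after filtering")
    attr(mask, "empty_warning") <- TRUE
  }
  mask
}

#' Nucleus and exNuc masks inside a cell
#'
#' Computes the diffuse-septin / low-MT nucleus score
#' `nuc_score = smooth(SEP) * (1 - smooth(MT))` on channels min-max
#' normalized over the cell voxels, triangle-thresholds it within the
#' cell, and retains candidate components only when their median raw MT is
#' strictly below `mt_median_fraction` times the cell-wide raw MT median.
#' All retained components form the nucleus; `exnuc = cell AND NOT
#' nucleus`. When no candidate passes, the nucleus is empty and `exnuc`
#' equals the cell (a valid outcome).
#'
#' @param pair A [field_pair()].
#' @param cell Logical cell mask (non-empty).
#' @param params A [masking_params()].
#' @return Object of class `segmentation_masks`: list with logical arrays
#'   `cell`, `nucleus`, `exnuc`.
#' @export
compute_nucleus_mask <- function(pair, cell, params = masking_params()) {
  stopifnot(inherits(pair, "field_pair"))
  cell <- .as_vol(cell)
  if (!any(cell)) stop("cell mask is empty")
  g <- pair$sep$geometry
  s_sep <- gaussian_smooth(pair$sep$values, params$nuc_smooth_sigma_nm, g)
  s_mt <- gaussian_smooth(pair$mt$values, params$nuc_smooth_sigma_nm, g)
  norm01 <- function(v) {
    inside <- v[cell]
    lo <- min(inside); hi <- max(inside)
    if (hi - lo <= 0) return(array(0, dim(v)))
    pmin(pmax((v - lo) / (hi - lo), 0), 1)
  }
  score <- norm01(s_sep) * (1 - norm01(s_mt))
  thr <- triangle_threshold(as.numeric(score[cell]))
  cand <- array(score > thr, dim(cell)) & cell
  nucleus <- array(FALSE, dim(cell))
  if (any(cand)) {
    lab <- label_components(cand, 26)
    mt_raw <- pair$mt$values
    cell_median <- median(mt_raw[cell])
    for (cid in seq_len(max(lab))) {
      inside <- lab == cid
      if (median(mt_raw[inside]) < params$mt_median_fraction * cell_median)
        nucleus <- nucleus | inside
    }
  }
  structure(list(cell = cell, nucleus = nucleus,
                 exnuc = cell & !nucleus),
            class = "segmentation_masks")
}

#' @export
print.segmentation_masks <- function(x, ...) {
  cat(sprintf("segmentation_masks: cell %d, nucleus %d, exNuc %d voxels\n",
              sum(x$cell), sum(x$nucleus), sum(x$exnuc)))
  invisible(x)
}
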