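# Threshold rules: triangle (geometric), robust MAD, Otsu (via EBImage,
# kept for comparison and for the neurite mask), and hysteresis growth.

#' Triangle threshold
#'
#' Zack's triangle algorithm on a fixed-bin histogram: the threshold is the
#' intensity that maximizes the perpendicular distance between the
#' histogram profile and the straight line joining the histogram peak to
#' the farthest empty tail bin. Suited to strongly skewed foreground/
#' background mixtures where Otsu's bimodality assumption fails.
#'
#' @param values Numeric vector of intensities (non-empty, finite).
#' @param bins Number of histogram bins (default 256).
#' @return Scalar threshold on the intensity scale. A constant input
#'   returns that constant with attribute `degenerate = TRUE`.
#' @examples
#' x <- c(rnorm(10000, 10), rnorm(500, 100))
#' triangle_threshold(x)
#' @export
triangle_threshold <- function(values, bins = 256L) {
  values <- as.numeric(values)
  if (length(values) == 0) stop("empty sample")
  if (!all(is.finite(values))) stop("sample must be finite")
  lo <- min(values); hi <- max(values)
  if (hi - lo <= .Machine$double.eps * max(abs(hi), 1)) {
    return(structure(lo, degenerate = TRUE))
  }
  h <- tabulate(pmin(bins, as.integer((values - lo) / (hi - lo) * bins) + 1L),
                nbins = bins)
  peak <- which.max(h)
  # the farthest empty (or last occupied) bin on the longer tail
  nz <- which(h > 0)
  left_span <- peak - nz[1]
  right_span <- nz[length(nz)] - peak
  if (right_span >= left_span) {
    tail_bin <- nz[length(nz)]
    idx <- peak:tail_bin
  } else {
    tail_bin <- nz[1]
    idx <- peak:tail_bin
  }
  if (length(idx) < 3) {
    thr_bin <- peak
  } else {
    # perpendicular distance of (i, h[i]) from the line peak -> tail
    x1 <- peak; y1 <- h[peak]; x2 <- tail_bin; y2 <- h[tail_bin]
    d <- abs((y2 - y1) * idx - (x2 - x1) * h[idx] + x2 * y1 - y2 * x1)
    thr_bin <- idx[which.max(d)]
  }
  lo + (thr_bin - 0.5) / bins * (hi - lo)
}

#' Robust MAD threshold
#'
#' `median + 5 * 1.4826 * MAD` of the sample, where MAD is the median
#' absolute deviation. Since `1.4826 * MAD` is a consistent estimator of
#' the Gaussian standard deviation, this sits approximately five sigma
#' above the noise floor while being insensitive to bright outliers
#' (unlike Otsu).
#'
#' @param values Numeric vector (non-empty).
#' @param k Multiplier of the robust sigma (default 5).
#' @return Scalar threshold. Constant input returns that constant.
#' @examples
#' mad_threshold(1:9)  # 5 + 5 * 1.4826 * 2 = 19.826
#' @export
mad_threshold <- function(values, k = 5) {
  values <- as.numeric(values)
  if (length(values) == 0) stop("empty sample")
  med <- median(values)
  med + k * 1.4826 * median(abs(values - med))
}

#' Otsu threshold (wrapper)
#'
#' Thin wrapper around `EBImage::otsu()` on an intensity-normalized copy,
#' returned on the original intensity scale. Used by the neurite mask
#' (scaled by 0.35) and, in validation, as the comparison method whose
#' sensitivity to bright outliers motivates the MAD rule.
#'
#' @param values Numeric vector or array.
#' @param bins Number of histogram levels (default 256).
#' @return Scalar threshold on the input scale.
#' @export
otsu_threshold <- function(values, bins = 256L) {
  v <- as.numeric(values)
  lo <- min(v); hi <- max(v)
  if (hi - lo <= .Machine$double.eps * max(abs(hi), 1))
    return(structure(lo, degenerate = TRUE))
  v01 <- matrix((v - lo) / (hi - lo), nrow = 1L)
  t01 <- EBImage::otsu(v01, range = c(0, 1), levels = bins)
  lo + t01 * (hi - lo)
}

#' Hysteresis thresholding
#'
#' Voxels at or above `high` (inside `within`, when given) seed region
#' growth through 26-connected voxels at or above `low`. With
#' `low == high` this collapses to a simple threshold.
#'
#' @param response Numeric matrix or 3-D array (e.g., a vesselness map).
#' @param low,high Thresholds with `low <= high`.
#' @param within Optional logical array restricting both seeds and growth.
#' @return Logical array.
#' @export
hysteresis_mask <- function(response, low, high, within = NULL) {
  if (low > high) stop("low must not exceed high")
  r <- .as_vol(response)
  lowmask <- r >= low
  seeds <- r >= high
  if (!is.null(within)) {
    w <- .as_vol(within)
    lowmask <- lowmask & w
    seeds <- seeds & w
  }
  if (!any(seeds)) return(array(FALSE, dim(r)))
  lab <- label_components(lowmask, 26)
  keep <- unique(lab[seeds])
  keep <- keep[keep > 0]
  array(lab %in% keep, dim(r))
}
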