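# Spectral bleed-through of the cytoskeleton channel into the septin
# channel: background estimation, slope estimation on signal-free voxels,
# and the correction SEP_corr = max(0, SEP - alpha * MT).

#' Bounds on the accepted bleed slope
#'
#' @param cap Slopes above `cap` but at most `reject_above` are capped to
#'   `cap` (status `"capped"`). Default 0.30: typical filter-set crosstalk
#'   is well below 30 percent.
#' @param reject_above Slopes above this indicate diffuse cytoplasmic
#'   septin rather than spectral bleed; the field is flagged `"rejected"`
#'   and no correction is applied. Default 0.60.
#' @return Object of class `bleed_bounds`.
#' @export
bleed_bounds <- function(cap = 0.30, reject_above = 0.60) {
  stopifnot(cap > 0, cap <= reject_above)
  structure(list(cap = cap, reject_above = reject_above),
            class = "bleed_bounds")
}

#' Per-channel background from outside the cell
#'
#' Background is the median intensity over voxels outside the cell mask.
#' When fewer than `min_outside` voxels lie outside the cell, falls back
#' to the 1st percentile inside the cell and flags the result.
#'
#' @param pair A [field_pair()].
#' @param cell Logical cell mask.
#' @param min_outside Minimum outside-voxel count for the median path
#'   (default 100).
#' @return List `bg_sep`, `bg_mt`, `fallback` (logical flag).
#' @export
estimate_background <- function(pair, cell, min_outside = 100) {
  stopifnot(inherits(pair, "field_pair"))
  cell <- .as_vol(cell)
  outside <- !cell
  if (sum(outside) >= min_outside) {
    list(bg_sep = median(pair$sep$values[outside]),
         bg_mt = median(pair$mt$values[outside]),
         fallback = FALSE)
  } else {
    list(bg_sep = unname(quantile(pair$sep$values[cell], 0.01)),
         bg_mt = unname(quantile(pair$mt$values[cell], 0.01)),
         fallback = TRUE)
  }
}

#' Estimate the bleed-through slope alpha
#'
#' On the cytoplasmic (exNuc) voxels least likely to carry true septin
#' signal - those whose raw SEP intensity is at or below the 25th
#' percentile of SEP over exNuc - and whose background-subtracted MT
#' exceeds a positivity floor, the slope is the median of the per-voxel
#' ratios `(SEP - bg_sep) / (MT - bg_mt)`. The floor (default twice the
#' robust noise SD of the MT background) prevents ratio blow-up on
#' near-background voxels. The estimate is capped / rejected per
#' [bleed_bounds()].
#'
#' @param pair A [field_pair()].
#' @param exnuc Logical cytoplasm mask (cell minus nucleus), non-empty.
#' @param bg Output of [estimate_background()] (or a list with `bg_sep`,
#'   `bg_mt`).
#' @param bounds A [bleed_bounds()].
#' @param min_voxels Minimum selected-voxel count for an accepted estimate
#'   (default 50).
#' @param floor_k Positivity floor in units of the robust MT background
#'   noise SD (default 2).
#' @return Object of class `bleed_estimate`: `alpha`, `bg_sep`, `bg_mt`,
#'   `n_voxels_used`, `status` in `{"accepted", "capped", "rejected"}`,
#'   and `reason` when rejected.
#' @export
estimate_bleed_slope <- function(pair, exnuc, bg, bounds = bleed_bounds(),
                                 min_voxels = 50, floor_k = 2) {
  stopifnot(inherits(pair, "field_pair"), inherits(bounds, "bleed_bounds"))
  exnuc <- .as_vol(exnuc)
  if (!any(exnuc)) stop("exnuc mask is empty")
  sep <- pair$sep$values[exnuc]
  mt <- pair$mt$values[exnuc]
  # robust noise SD of the MT background: MAD over the dim half of the
  # volume (dominated by background voxels)
  mt_bgpop <- pair$mt$values[pair$mt$values <= quantile(pair$mt$values, 0.5)]
  noise_sd <- 1.4826 * median(abs(mt_bgpop - median(mt_bgpop)))
  q25 <- quantile(sep, 0.25)
  sel <- sep <= q25 & (mt - bg$bg_mt) > floor_k * noise_sd
  n <- sum(sel)
  mk <- function(alpha, status, n, reason = NA_character_) {
    structure(list(alpha = alpha, bg_sep = bg$bg_sep, bg_mt = bg$bg_mt,
                   n_voxels_used = n, status = status, reason = reason),
              class = "bleed_estimate")
  }
  if (n < min_voxels)
    return(mk(NA_real_, "rejected", n,
              sprintf("only %d voxels above the MT positivity floor", n)))
  alpha <- median((sep[sel] - bg$bg_sep) / (mt[sel] - bg$bg_mt))
  alpha <- max(0, alpha)
  if (alpha > bounds$reject_above)
    return(mk(alpha, "rejected", n,
              "slope above reject bound: diffuse septin, not bleed"))
  if (alpha > bounds$cap) return(mk(bounds$cap, "capped", n))
  mk(alpha, "accepted", n)
}

#' @export
print.bleed_estimate <- function(x, ...) {
  cat(sprintf("bleed_estimate: alpha = %s (%s), n = %d, bg = (%.2f, %.2f)\n",
              ifelse(is.na(x$alpha), "NA", sprintf("%.4f", x$alpha)),
              x$status, x$n_voxels_used, x$bg_sep, x$bg_mt))
  if (!is.na(x$reason)) cat("  reason:", x$reason, "\n")
  invisible(x)
}

#' Apply the bleed correction
#'
#' Voxelwise `SEP_corr = max(0, SEP - alpha * MT)`. Only accepted or
#' capped estimates may be applied.
#'
#' @param pair A [field_pair()].
#' @param estimate A `bleed_estimate` with status `"accepted"` or
#'   `"capped"`.
#' @return Numeric array (corrected SEP), same shape and geometry.
#' @export
correct_bleed <- function(pair, estimate) {
  stopifnot(inherits(pair, "field_pair"), inherits(estimate, "bleed_estimate"))
  if (!estimate$status %in% c("accepted", "capped"))
    stop("bleed estimate was rejected; skip the correction for this field")
  pmax(pair$sep$values - estimate$alpha * pair$mt$values, 0)
}
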