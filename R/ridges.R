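# Curvilinear-structure enhancement: scale-normalized Gaussian Hessians,
# closed-form (Cardano) eigenvalues, 3-D Frangi vesselness and 2-D Sato
# ridge response.

#' Ridge-filter parameters
#'
#' Bundles the tunable parameters of the curvilinear enhancement stack.
#' Frangi scales are physical tube radii in nm bracketing a PSF-blurred
#' microtubule; Sato sigmas are in pixels (the 2-D actin quantifier is
#' defined in pixel units).
#'
#' @param frangi_scales_nm Three increasing physical scales (nm).
#' @param frangi_alpha,frangi_beta Plate/blob sensitivity constants.
#' @param frangi_c Structureness constant, or `NULL` for the standard
#'   auto rule (half the maximum Hessian norm per scale).
#' @param hysteresis_low_q,hysteresis_high_q Response quantiles (within the
#'   cell mask) used as hysteresis levels in quantile mode.
#' @param sato_sigmas_px Ordered positive Sato scales in pixels.
#' @param tophat_radii_nm Ellipsoid radius of the white top-hat (nm).
#' @param highpass_sigma_nm Sigma of the Gaussian high-pass (nm).
#' @return Object of class `ridge_params`.
#' @export
ridge_params <- function(frangi_scales_nm = c(150, 250, 400),
                         frangi_alpha = 0.5, frangi_beta = 0.5,
                         frangi_c = NULL,
                         hysteresis_low_q = 0.90, hysteresis_high_q = 0.98,
                         sato_sigmas_px = c(1.5, 2.5, 4, 6, 8),
                         tophat_radii_nm = 500,
                         highpass_sigma_nm = 2000) {
  stopifnot(length(frangi_scales_nm) == 3, all(frangi_scales_nm > 0),
            all(diff(frangi_scales_nm) > 0),
            all(sato_sigmas_px > 0), all(diff(sato_sigmas_px) > 0),
            hysteresis_low_q < hysteresis_high_q)
  structure(list(frangi_scales_nm = frangi_scales_nm,
                 frangi_alpha = frangi_alpha, frangi_beta = frangi_beta,
                 frangi_c = frangi_c,
                 hysteresis_low_q = hysteresis_low_q,
                 hysteresis_high_q = hysteresis_high_q,
                 sato_sigmas_px = sato_sigmas_px,
                 tophat_radii_nm = tophat_radii_nm,
                 highpass_sigma_nm = highpass_sigma_nm),
            class = "ridge_params")
}

# the six second-derivative volumes at one physical scale, gamma-normalized
# by the (lateral) scale in pixels squared so responses are comparable
# across scales
.hessian_3d <- function(vol, scale_nm, geometry) {
  sx <- scale_nm / geometry$dx
  sy <- scale_nm / geometry$dy
  sz <- scale_nm / geometry$dz
  d <- dim(vol)
  flat <- is2d <- d[3] == 1L
  gam <- sx^2
  H <- list(
    xx = .gauss_sep(vol, c(sx, sy, sz), c(2L, 0L, 0L)),
    yy = .gauss_sep(vol, c(sx, sy, sz), c(0L, 2L, 0L)),
    xy = .gauss_sep(vol, c(sx, sy, sz), c(1L, 1L, 0L))
  )
  if (!flat) {
    H$zz <- .gauss_sep(vol, c(sx, sy, sz), c(0L, 0L, 2L))
    H$xz <- .gauss_sep(vol, c(sx, sy, sz), c(1L, 0L, 1L))
    H$yz <- .gauss_sep(vol, c(sx, sy, sz), c(0L, 1L, 1L))
  } else {
    zero <- array(0, d)
    H$zz <- zero; H$xz <- zero; H$yz <- zero
  }
  lapply(H, function(h) h * gam)
}

#' Hessian eigenvalues by the analytic Cardano solution
#'
#' Computes the scale-normalized Gaussian Hessian of a 3-D grid at one
#' physical scale (axial sigma scaled by the z/xy voxel ratio) and returns
#' per-voxel eigenvalues obtained in closed form via the trigonometric
#' (Cardano) solution of the characteristic cubic, ordered
#' `|lam1| <= |lam2| <= |lam3|`.
#'
#' @param x `channel_stack`, matrix or 3-D array.
#' @param scale_nm Physical scale (Gaussian derivative sigma) in nm.
#' @param geometry Voxel geometry when `x` is a bare array.
#' @return List of arrays `lam1`, `lam2`, `lam3`.
#' @export
hessian_eigs_cardano <- function(x, scale_nm, geometry = NULL) {
  g <- .geom(x, geometry)
  v <- .values(x)
  H <- .hessian_3d(v, scale_nm, g)
  e <- .eig3_cardano(as.numeric(H$xx), as.numeric(H$yy), as.numeric(H$zz),
                     as.numeric(H$xy), as.numeric(H$xz), as.numeric(H$yz))
  d <- dim(v)
  list(lam1 = array(e$lam1, d), lam2 = array(e$lam2, d),
       lam3 = array(e$lam3, d))
}

#' 3-D Frangi vesselness (bright ridges)
#'
#' Multiscale vesselness in the Frangi (1998) form, using the analytic
#' Cardano Hessian eigendecomposition at three physical scales; the final
#' response is the voxelwise maximum over scales and lies in \[0, 1\].
#' Ridge ratios: `Ra = |lam2|/|lam3|` (plate vs line), `Rb =
#' |lam1|/sqrt(|lam2 lam3|)` (blobness), `S = ||lambda||` (structureness);
#' response is zero wherever `lam2 > 0` or `lam3 > 0` (dark structures).
#'
#' @param x `channel_stack`, matrix or 3-D array.
#' @param params A [ridge_params()].
#' @param geometry Voxel geometry when `x` is a bare array.
#' @return Numeric array in \[0, 1\].
#' @export
frangi_3d <- function(x, params = ridge_params(), geometry = NULL) {
  g <- .geom(x, geometry)
  v <- .values(x)
  d <- dim(v)
  out <- array(0, d)
  for (s in params$frangi_scales_nm) {
    H <- .hessian_3d(v, s, g)
    e <- .eig3_cardano(as.numeric(H$xx), as.numeric(H$yy), as.numeric(H$zz),
                       as.numeric(H$xy), as.numeric(H$xz), as.numeric(H$yz))
    cc <- params$frangi_c
    if (is.null(cc)) {
      smax <- sqrt(max(e$lam1^2 + e$lam2^2 + e$lam3^2))
      cc <- if (smax > 0) smax / 2 else 1
    }
    r <- .frangi_response(e$lam1, e$lam2, e$lam3,
                          params$frangi_alpha, params$frangi_beta, cc)
    out <- pmax(out, array(r, d))
  }
  out
}

#' 2-D Sato ridge response (bright ridges)
#'
#' Multiscale line filter from the 2-D scale-normalized Hessian: at each
#' scale the response is `-lam2` where `lam2` (the principal eigenvalue of
#' larger magnitude) is negative, zero otherwise; the output is the
#' pixelwise maximum over scales. Enhances tubular structures and
#' suppresses isotropic puncta.
#'
#' @param image Numeric matrix (single-channel 2-D field).
#' @param sigmas_px Positive scales in pixels (default the actin-bundle
#'   scales 1.5, 2.5, 4, 6, 8).
#' @return Numeric matrix of the same shape, non-negative.
#' @export
sato_2d <- function(image, sigmas_px = c(1.5, 2.5, 4, 6, 8)) {
  if (length(dim(image)) != 2) stop("expected a 2-D image")
  stopifnot(all(sigmas_px > 0))
  v <- .as_vol(image)
  d <- dim(v)
  out <- array(0, d)
  for (s in sigmas_px) {
    hxx <- .gauss_sep(v, c(s, s, 1), c(2L, 0L, 0L)) * s^2
    hyy <- .gauss_sep(v, c(s, s, 1), c(0L, 2L, 0L)) * s^2
    hxy <- .gauss_sep(v, c(s, s, 1), c(1L, 1L, 0L)) * s^2
    # closed-form 2x2 symmetric eigenvalues; bright-ridge line measure
    # in Sato's form: |lam_lo| reduced by the second eigenvalue so that
    # isotropic blobs (lam_hi ~ lam_lo < 0) are suppressed while ridges
    # (lam_hi ~ 0) keep their full response
    tr <- hxx + hyy
    dt <- sqrt(pmax((hxx - hyy)^2 / 4 + hxy^2, 0))
    lam_lo <- tr / 2 - dt
    lam_hi <- tr / 2 + dt
    base <- ifelse(lam_lo < 0, -lam_lo, 0)
    penalty <- ifelse(lam_hi < 0, -lam_hi, 0.25 * lam_hi)
    resp <- pmax(base - penalty, 0)
    out <- pmax(out, resp)
  }
  matrix(out, d[1], d[2])
}
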