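# Synthetic phantom generators with exact ground truth. These emulate the
# statistical structure of the acquisitions the analysis assumes - 3-D
# spinning-disk-like two-channel stacks with curvilinear filaments, and
# 2-D fields of actin ribbons or neurons - so that every downstream stage
# can be validated without external data.

#' Specification of a 3-D two-channel filament phantom
#'
#' Defaults emulate a spinning-disk acquisition at 108 x 108 x 200 nm
#' voxels: gently curved filaments in both channels with a configurable
#' coincident fraction, a diffuse cytoplasmic tubulin pool inside an
#' ellipsoidal cell body, an optional diffuse-septin / low-tubulin
#' nucleus, anisotropic Gaussian PSF blur, linear channel bleed, and
#' Poisson shot noise followed by Gaussian read noise.
#'
#' @param shape Grid dimensions in voxels, `c(nx, ny, nz)`.
#' @param geometry A [voxel_geometry()] (default 108/108/200 nm).
#' @param n_mt_filaments,n_sep_filaments Filament counts per channel.
#' @param coincidence_fraction Fraction of septin filaments laid exactly
#'   on microtubule filaments, in \[0, 1\].
#' @param min_separation_um Minimum distance of non-coincident septin
#'   centerlines from microtubule centerlines (default 1 um).
#' @param filament_intensity Peak photons/voxel per filament.
#' @param psf_sigma_xy_nm,psf_sigma_z_nm Gaussian PSF sigmas (defaults 90
#'   and 250 nm, consistent with a ~220 nm lateral FWHM).
#' @param alpha_true Bleed slope of MT into SEP, in \[0, 1).
#' @param read_noise_sd Gaussian read noise SD (counts).
#' @param background_level Constant per-channel offset (counts).
#' @param cytoplasm_mt_level Mean diffuse tubulin-pool signal inside the
#'   cell body (photons/voxel), realized as a smoothly varying spatial
#'   field; gives the cell a body and the cytoplasm a realistic broad
#'   intensity distribution.
#' @param cytoplasm_sep_level Diffuse septin-pool signal in occupied
#'   cytoplasm; occupancy is a sharp smooth-field threshold leaving a
#'   small fraction of the cytoplasm septin-free.
#' @param include_nucleus Add a diffuse-septin, tubulin-free nuclear blob.
#' @param nucleus_sep_level Diffuse septin level inside the nucleus.
#' @param min_length_um Minimum filament length (default 5 um).
#' @param max_turn_deg Per-step turning angle bound (default 15 degrees).
#' @param shot_noise Apply Poisson shot noise (default `TRUE`; with
#'   `FALSE` and `read_noise_sd = 0` the grids are the exact noise-free
#'   limit).
#' @param denoise_sigma_nm Sub-voxel Gaussian applied after the camera
#'   noise (default 80 nm), emulating the denoised/deconvolved stacks
#'   the analysis consumes; 0 disables it.
#' @param seed Integer RNG seed; identical spec + seed gives bit-identical
#'   output.
#' @return Object of class `phantom_spec_3d`.
#' @export
phantom_spec_3d <- function(shape = c(128, 128, 16),
                            geometry = voxel_geometry(108, 108, 200),
                            n_mt_filaments = 30, n_sep_filaments = 8,
                            coincidence_fraction = 0.5,
                            min_separation_um = 1,
                            filament_intensity = 3000,
                            psf_sigma_xy_nm = 90, psf_sigma_z_nm = 250,
                            alpha_true = 0.05, read_noise_sd = 3,
                            background_level = 200,
                            cytoplasm_mt_level = 1000,
                            cytoplasm_sep_level = 1500,
                            include_nucleus = TRUE,
                            nucleus_sep_level = 3000,
                            min_length_um = 5, max_turn_deg = 15,
                            shot_noise = TRUE, denoise_sigma_nm = 80,
                            seed = 1L) {
  stopifnot(length(shape) == 3, all(shape >= c(32, 32, 8)),
            coincidence_fraction >= 0, coincidence_fraction <= 1,
            alpha_true >= 0, filament_intensity >= 0,
            background_level >= 0, read_noise_sd >= 0)
  if (alpha_true >= 1) stop("alpha_true must be below 1")
  structure(as.list(environment()), class = "phantom_spec_3d")
}

# one smooth 3-D polyline: bounded-curvature random walk inside the cell
# ellipsoid, avoiding the nucleus; returns n x 3 matrix in voxel coords
.random_polyline_3d <- function(spec, inside, step_vox = 0.5) {
  d <- spec$shape
  g <- spec$geometry
  n_steps <- ceiling(spec$min_length_um * 1000 / (step_vox * g$dx) * 1.5)
  for (try in 1:50) {
    p <- c(runif(1, d[1] * 0.15, d[1] * 0.85),
           runif(1, d[2] * 0.15, d[2] * 0.85),
           runif(1, d[3] * 0.25, d[3] * 0.75))
    if (!inside(p)) next
    theta <- runif(1, 0, 2 * pi)
    phi <- runif(1, -0.25, 0.25)  # mostly in-plane, like adherent cells
    dir <- c(cos(theta) * cos(phi), sin(theta) * cos(phi), sin(phi))
    pts <- matrix(0, n_steps + 1, 3)
    pts[1, ] <- p
    ok <- TRUE
    max_turn <- spec$max_turn_deg * pi / 180
    for (i in seq_len(n_steps)) {
      # random small rotation of the direction
      ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
      ang <- runif(1, -max_turn, max_turn) * step_vox
      dir <- dir * cos(ang) + pracma_cross(ax, dir) * sin(ang) +
        ax * sum(ax * dir) * (1 - cos(ang))
      dir <- dir / sqrt(sum(dir^2))
      # physical step of step_vox * dx nm; convert to voxel units per axis
      stp <- dir * step_vox * g$dx / c(g$dx, g$dy, g$dz)
      cand <- pts[i, ] + stp
      if (!inside(cand)) {
        # reflect laterally, keep going
        dir <- -dir
        cand <- pts[i, ] + dir * step_vox * g$dx / c(g$dx, g$dy, g$dz)
        if (!inside(cand)) { ok <- i > n_steps * 0.6; break }
      }
      pts[i + 1, ] <- cand
      if (i == n_steps) break
    }
    n_done <- max(which(rowSums(abs(pts)) > 0))
    if (ok && n_done >= n_steps * 0.6) return(pts[1:n_done, , drop = FALSE])
  }
  stop("could not place a filament; shape too small for min_length_um")
}

# minimal cross product (avoids a dependency for one formula)
pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# rasterize polyline points to unique voxel indices within the grid
.rasterize <- function(pts, d) {
  v <- round(pts)
  keep <- v[, 1] >= 1 & v[, 1] <= d[1] & v[, 2] >= 1 & v[, 2] <= d[2] &
    v[, 3] >= 1 & v[, 3] <= d[3]
  v <- v[keep, , drop = FALSE]
  unique(v)
}

#' Generate a 3-D two-channel filament phantom
#'
#' Builds the stack in six steps: (1) smooth 3-D polylines sampled by a
#' bounded-curvature random walk, (2) rasterized centerlines (the truth
#' skeletons), (3) anisotropic Gaussian PSF convolution (axial sigma
#' scaled by the z/xy ratio), (4) constant background, (5) linear bleed
#' `SEP <- SEP + alpha_true * MT`, (6) Poisson shot noise then Gaussian
#' read noise. Truth masks are the centerlines dilated to the PSF FWHM.
#'
#' @param spec A [phantom_spec_3d()].
#' @return List with `pair` (a [field_pair()]) and `truth` (class
#'   `phantom_truth`): logical truth masks and skeletons per channel,
#'   `nucleus_true`, `cell_true`, `alpha_true`,
#'   `coincidence_fraction_true` (exact centerline-voxel fraction), and
#'   `filament_lengths_um`.
#' @export
make_filament_stack_3d <- function(spec = phantom_spec_3d()) {
  stopifnot(inherits(spec, "phantom_spec_3d"))
  set.seed(spec$seed)
  d <- spec$shape
  g <- spec$geometry
  # cell body: axis-aligned ellipsoid filling most of the grid
  ctr <- (d + 1) / 2
  # the stack is a mid-cell axial substack (a few um of a much taller
  # cell), so cell and nucleus extend beyond the axial crop
  # laterally the crop hugs the cell, as an analyst crops a field
  semi <- c(d[1] * 0.50, d[2] * 0.50, d[3] * 1.2)
  nuc_semi <- c(d[1] * 0.24, d[2] * 0.24, d[3] * 0.75)
  in_cell <- function(p) sum(((p - ctr) / semi)^2) <= 1
  in_nuc <- function(p) sum(((p - ctr) / nuc_semi)^2) <= 1
  inside <- if (spec$include_nucleus) {
    function(p) in_cell(p) && !in_nuc(p)
  } else in_cell
  xg <- seq_len(d[1]); yg <- seq_len(d[2]); zg <- seq_len(d[3])
  ex <- outer((xg - ctr[1]) / semi[1], (yg - ctr[2]) / semi[2],
              function(a, b) a^2 + b^2)
  cell_true <- array(FALSE, d)
  nucleus_true <- array(FALSE, d)
  for (z in zg) {
    cell_true[, , z] <- ex + ((z - ctr[3]) / semi[3])^2 <= 1
    nucleus_true[, , z] <-
      outer((xg - ctr[1]) / nuc_semi[1], (yg - ctr[2]) / nuc_semi[2],
            function(a, b) a^2 + b^2) + ((z - ctr[3]) / nuc_semi[3])^2 <= 1
  }
  if (!spec$include_nucleus) nucleus_true[] <- FALSE

  mt_centers <- array(FALSE, d)
  mt_polys <- list()
  for (i in seq_len(spec$n_mt_filaments)) {
    poly <- .random_polyline_3d(spec, inside)
    mt_polys[[i]] <- poly
    vox <- .rasterize(poly, d)
    mt_centers[vox] <- TRUE
  }
  # septin filaments: coincident ones reuse MT polylines; disjoint ones
  # keep min_separation_um from the MT centerlines
  n_coin <- round(spec$coincidence_fraction * spec$n_sep_filaments)
  sep_centers <- array(FALSE, d)
  if (n_coin > 0 && spec$n_mt_filaments > 0) {
    reuse <- sample(seq_len(spec$n_mt_filaments),
                    min(n_coin, spec$n_mt_filaments))
    if (n_coin > spec$n_mt_filaments)
      reuse <- c(reuse, sample(seq_len(spec$n_mt_filaments),
                               n_coin - spec$n_mt_filaments, replace = TRUE))
    for (i in reuse) sep_centers[.rasterize(mt_polys[[i]], d)] <- TRUE
  }
  n_free <- spec$n_sep_filaments - n_coin
  if (n_free > 0) {
    mt_dist <- if (any(mt_centers))
      distance_to_mask(mt_centers, g) else array(Inf, d)
    min_sep_nm <- spec$min_separation_um * 1000
    placed <- 0
    attempts <- 0
    while (placed < n_free && attempts < 50 * n_free) {
      attempts <- attempts + 1
      poly <- .random_polyline_3d(spec, inside)
      vox <- .rasterize(poly, d)
      if (any(mt_centers) && min(mt_dist[vox]) < min_sep_nm) next
      sep_centers[vox] <- TRUE
      placed <- placed + 1
    }
    if (placed < n_free)
      warning("placed only ", placed, " of ", n_free,
              " separated septin filaments")
  }

  # intensity rasters before optics; centerline amplitude is scaled so
  # that the post-PSF ridge peak of an isolated straight filament equals
  # filament_intensity (a line is diluted only transversally by the PSF)
  ky0 <- max(.gauss_kernel(spec$psf_sigma_xy_nm / g$dy))
  kz0 <- max(.gauss_kernel(spec$psf_sigma_z_nm / g$dz))
  line_amp <- spec$filament_intensity / (ky0 * kz0)
  mt_signal <- array(0, d)
  mt_signal[mt_centers] <- line_amp
  # diffuse cytoplasmic pools vary smoothly in space (as soluble tubulin
  # and septin pools do in real cytoplasm); the septin pool has a zero
  # floor so a minority of cytoplasm is genuinely septin-free, which is
  # what the bleed estimator's lowest-quartile selection relies on
  smooth_field <- function(scale_nm, shift) {
    z <- .gauss_sep(array(rnorm(prod(d)), d),
                    c(scale_nm / g$dx, scale_nm / g$dy, scale_nm / g$dz))
    z <- (z - mean(z)) / stats::sd(z)
    f <- pmax(z + shift, 0)
    f / mean(f)
  }
  cyto <- cell_true & !nucleus_true
  # the tubulin pool tapers to zero over ~0.8 um at the thin periphery;
  # the septin pool is additionally absent from a ~1.5 um cortical band
  # (septin-free lamella traversed by microtubules) and switches on
  # sharply inside - the septin-dim, tubulin-positive population the
  # bleed estimator's quartile selection relies on
  d_in <- distance_to_mask(!cell_true, g)
  taper_mt <- array(pmin(d_in / 800, 1), d)
  band_sep <- array(stats::plogis((d_in - 1500) / 150), d)
  mt_haze <- spec$cytoplasm_mt_level * smooth_field(1500, 1.6) * taper_mt
  if (spec$include_nucleus) {
    # perinuclear enrichment: microtubule density peaks around the
    # nucleus (the MTOC sits beside it), falling off over ~2 um
    d_nuc <- distance_to_mask(nucleus_true, g)
    mt_haze <- mt_haze * (1 + 0.8 * exp(-(d_nuc / 2000)^2))
  }
  mt_signal[cyto] <- mt_signal[cyto] + mt_haze[cyto]
  sep_signal <- array(0, d)
  sep_signal[sep_centers] <- line_amp
  # septin occupancy is near-binary: most cytoplasm carries a clear
  # diffuse pool, about a fifth is septin-free, with a sharp transition -
  # the population structure the bleed estimator's quartile cut presumes
  zf <- .gauss_sep(array(rnorm(prod(d)), d),
                   c(1500 / g$dx, 1500 / g$dy, 1500 / g$dz))
  zf <- (zf - mean(zf)) / stats::sd(zf)
  occupancy <- stats::plogis((zf - stats::qnorm(0.05)) / 0.12)
  sep_pool <- spec$cytoplasm_sep_level * occupancy * band_sep
  sep_signal[cyto] <- sep_signal[cyto] + sep_pool[cyto]
  if (spec$include_nucleus)
    sep_signal[nucleus_true] <- sep_signal[nucleus_true] +
      spec$nucleus_sep_level

  # PSF blur, isotropic in physical units via per-axis sigma in voxels
  blur <- function(v) {
    .gauss_sep(v, c(spec$psf_sigma_xy_nm / g$dx, spec$psf_sigma_xy_nm / g$dy,
                    spec$psf_sigma_z_nm / g$dz))
  }
  mt <- blur(mt_signal) + spec$background_level
  sep <- blur(sep_signal) + spec$background_level
  sep <- sep + spec$alpha_true * mt

  # camera model: Poisson shot noise then Gaussian read noise; with
  # shot_noise = FALSE and read_noise_sd = 0 the grids equal the
  # PSF-convolved rasters plus background exactly (noise-free limit)
  noisy <- function(v) {
    out <- v
    if (spec$shot_noise)
      out <- array(rpois(length(v), pmax(0, v)), dim(v))
    if (spec$read_noise_sd > 0)
      out <- out + array(rnorm(length(v), 0, spec$read_noise_sd), dim(v))
    pmax(out, 0)
  }
  mt_out <- noisy(mt)
  sep_out <- noisy(sep)
  if (spec$denoise_sigma_nm > 0) {
    dn <- function(v) .gauss_sep(v, c(spec$denoise_sigma_nm / g$dx,
                                      spec$denoise_sigma_nm / g$dy,
                                      spec$denoise_sigma_nm / g$dz))
    mt_out <- dn(mt_out)
    sep_out <- dn(sep_out)
  }

  fwhm_xy <- 2.355 * spec$psf_sigma_xy_nm / 2
  fwhm_z <- 2.355 * spec$psf_sigma_z_nm / 2
  mt_mask_true <- if (any(mt_centers))
    binary_dilate(mt_centers, fwhm_xy, g, fwhm_z) else mt_centers
  sep_mask_true <- if (any(sep_centers))
    binary_dilate(sep_centers, fwhm_xy, g, fwhm_z) else sep_centers

  n_sep_vox <- sum(sep_centers)
  coin_true <- if (n_sep_vox > 0) sum(sep_centers & mt_centers) / n_sep_vox
  else NA_real_

  pair <- field_pair(channel_stack(sep_out, g, "SEP"),
                     channel_stack(mt_out, g, "MT"))
  truth <- structure(list(
    mt_mask_true = mt_mask_true, sep_mask_true = sep_mask_true,
    mt_skeleton_true = mt_centers, sep_skeleton_true = sep_centers,
    nucleus_true = nucleus_true, cell_true = cell_true,
    alpha_true = spec$alpha_true,
    coincidence_fraction_true = coin_true), class = "phantom_truth")
  list(pair = pair, truth = truth)
}
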