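# 2-D phantom generators: actin ribbon fields (bundle quantifier oracle)
# and neuron fields with growth cones (morphometry oracle).

# rasterize a thick straight segment: pixels within width/2 of the segment
.draw_segment <- function(canvas, p0, p1, width_px, value) {
  d <- dim(canvas)
  xr <- range(p0[1], p1[1]) + c(-1, 1) * (width_px / 2 + 2)
  yr <- range(p0[2], p1[2]) + c(-1, 1) * (width_px / 2 + 2)
  xs <- max(1, floor(xr[1])):min(d[1], ceiling(xr[2]))
  ys <- max(1, floor(yr[1])):min(d[2], ceiling(yr[2]))
  if (length(xs) == 0 || length(ys) == 0) return(canvas)
  v <- p1 - p0
  L2 <- sum(v^2)
  for (y in ys) {
    w <- xs - p0[1]
    t <- if (L2 > 0) pmin(1, pmax(0, (w * v[1] + (y - p0[2]) * v[2]) / L2)) else 0
    dx <- w - t * v[1]
    dy <- (y - p0[2]) - t * v[2]
    hit <- dx^2 + dy^2 <= (width_px / 2)^2
    canvas[xs[hit], y] <- pmax(canvas[xs[hit], y], value)
  }
  canvas
}

# rasterize a filled ellipse
.draw_ellipse <- function(canvas, center, a, b, theta, value) {
  d <- dim(canvas)
  r <- max(a, b) + 2
  xs <- max(1, floor(center[1] - r)):min(d[1], ceiling(center[1] + r))
  ys <- max(1, floor(center[2] - r)):min(d[2], ceiling(center[2] + r))
  ct <- cos(theta); st <- sin(theta)
  for (y in ys) {
    u <- ct * (xs - center[1]) + st * (y - center[2])
    w <- -st * (xs - center[1]) + ct * (y - center[2])
    hit <- (u / a)^2 + (w / b)^2 <= 1
    canvas[xs[hit], y] <- pmax(canvas[xs[hit], y], value)
  }
  canvas
}

#' Specification of a 2-D actin-bundle phantom field
#'
#' Ribbons of known width and length (narrow "singles" and wide
#' "bundles"), round aggregates (aspect ratio below 3) and isolated
#' bright puncta that stress the robust threshold, on a noisy constant
#' background.
#'
#' @param shape Field dimensions in pixels.
#' @param pixel_size_um Pixel size (default 0.108 um).
#' @param n_singles,n_bundles,n_aggregates,n_puncta Object counts.
#' @param single_width_px,bundle_width_px Ranges (min, max) of ribbon
#'   widths.
#' @param single_length_um,bundle_length_um Ranges of ribbon lengths.
#' @param aggregate_radius_px Range of aggregate radii.
#' @param ribbon_intensity,punctum_intensity Object amplitudes (counts
#'   above background).
#' @param background_level,noise_sd Background mean and Gaussian noise SD.
#' @param psf_sigma_px Gaussian blur applied to objects (not noise).
#' @param seed Integer RNG seed.
#' @return Object of class `bundle_field_spec`.
#' @export
bundle_field_spec <- function(shape = c(512, 512), pixel_size_um = 0.108,
                              n_singles = 10, n_bundles = 5,
                              n_aggregates = 3, n_puncta = 10,
                              single_width_px = c(2, 3),
                              bundle_width_px = c(14, 18),
                              single_length_um = c(11, 16),
                              bundle_length_um = c(12, 25),
                              aggregate_radius_px = c(8, 12),
                              ribbon_intensity = 150,
                              punctum_intensity = 4000,
                              background_level = 100, noise_sd = 15,
                              psf_sigma_px = 1, seed = 1L) {
  stopifnot(length(shape) == 2, all(shape >= 64), pixel_size_um > 0,
            single_width_px[1] >= 1, bundle_width_px[1] >= 1)
  structure(as.list(environment()), class = "bundle_field_spec")
}

#' Generate a 2-D actin-bundle phantom field
#'
#' Places non-overlapping ribbons, aggregates and puncta (bounded
#' retries; errors if the spec is too crowded), blurs objects with a
#' Gaussian PSF and adds Gaussian noise. The truth table records each
#' object's class, width, length and aspect ratio.
#'
#' @param spec A [bundle_field_spec()].
#' @return List with `image` (matrix) and `truth` (class `phantom_truth`)
#'   whose `object_table` has columns `id`, `class`, `length_um`,
#'   `width_px`.
#' @export
make_bundle_field_2d <- function(spec = bundle_field_spec()) {
  stopifnot(inherits(spec, "bundle_field_spec"))
  set.seed(spec$seed)
  d <- spec$shape
  signal <- matrix(0, d[1], d[2])
  occupied <- matrix(FALSE, d[1], d[2])
  objects <- list()
  margin <- 8
  place_ribbon <- function(width_px, length_px, klass) {
    for (try in 1:200) {
      theta <- runif(1, 0, pi)
      c0 <- c(runif(1, margin, d[1] - margin), runif(1, margin, d[2] - margin))
      h <- length_px / 2 * c(cos(theta), sin(theta))
      p0 <- c0 - h; p1 <- c0 + h
      if (any(c(p0, p1) < margin) || any(p0 > d - margin) ||
          any(p1 > d - margin)) next
      probe <- matrix(0, d[1], d[2])
      probe <- .draw_segment(probe, p0, p1, width_px + 26, 1)
      if (any(occupied & probe > 0)) next
      signal <<- .draw_segment(signal, p0, p1, width_px,
                               spec$ribbon_intensity)
      occupied <<- occupied | probe > 0
      objects[[length(objects) + 1]] <<- data.frame(
        class = klass, length_um = length_px * spec$pixel_size_um,
        width_px = width_px, aspect_ratio = length_px / width_px)
      return(TRUE)
    }
    FALSE
  }
  for (i in seq_len(spec$n_bundles)) {
    w <- runif(1, spec$bundle_width_px[1], spec$bundle_width_px[2])
    l <- runif(1, spec$bundle_length_um[1], spec$bundle_length_um[2]) /
      spec$pixel_size_um
    if (!place_ribbon(w, l, "bundle"))
      stop("could not place bundle ", i, ": field too crowded")
  }
  for (i in seq_len(spec$n_singles)) {
    w <- runif(1, spec$single_width_px[1], spec$single_width_px[2])
    l <- runif(1, spec$single_length_um[1], spec$single_length_um[2]) /
      spec$pixel_size_um
    if (!place_ribbon(w, l, "single"))
      stop("could not place single filament ", i, ": field too crowded")
  }
  for (i in seq_len(spec$n_aggregates)) {
    placed <- FALSE
    for (try in 1:200) {
      r <- runif(1, spec$aggregate_radius_px[1], spec$aggregate_radius_px[2])
      asp <- runif(1, 1, 1.6)  # aspect ratio < 3 by construction
      c0 <- c(runif(1, margin + r, d[1] - margin - r),
              runif(1, margin + r, d[2] - margin - r))
      probe <- matrix(0, d[1], d[2])
      probe <- .draw_ellipse(probe, c0, r * asp + 13, r + 13, 0, 1)
      if (any(occupied & probe > 0)) next
      th <- runif(1, 0, pi)
      signal <- .draw_ellipse(signal, c0, r * asp, r, th,
                              spec$ribbon_intensity)
      occupied <- occupied | probe > 0
      objects[[length(objects) + 1]] <- data.frame(
        class = "aggregate", length_um = 2 * r * asp * spec$pixel_size_um,
        width_px = 2 * r, aspect_ratio = asp)
      placed <- TRUE
      break
    }
    if (!placed) stop("could not place aggregate ", i, ": field too crowded")
  }
  for (i in seq_len(spec$n_puncta)) {
    for (try in 1:200) {
      c0 <- round(c(runif(1, margin, d[1] - margin),
                    runif(1, margin, d[2] - margin)))
      xs <- c0[1] + 0:1; ys <- c0[2] + 0:1
      if (any(occupied[xs - 2, ys - 2]) || any(occupied[xs + 2, ys + 2])) next
      signal[xs, ys] <- pmax(signal[xs, ys], spec$punctum_intensity)
      occupied[(c0[1] - 2):(c0[1] + 3), (c0[2] - 2):(c0[2] + 3)] <- TRUE
      objects[[length(objects) + 1]] <- data.frame(
        class = "puncta", length_um = 2 * spec$pixel_size_um, width_px = 2,
        aspect_ratio = 1)
      break
    }
  }
  if (spec$psf_sigma_px > 0)
    signal <- matrix(.gauss_sep(.as_vol(signal),
                                c(spec$psf_sigma_px, spec$psf_sigma_px, 1)),
                     d[1], d[2])
  image <- signal + spec$background_level +
    matrix(rnorm(prod(d), 0, spec$noise_sd), d[1], d[2])
  image <- pmax(image, 0)
  tab <- do.call(rbind, objects)
  if (is.null(tab)) tab <- data.frame(class = character(0),
                                      length_um = numeric(0),
                                      width_px = numeric(0),
                                      aspect_ratio = numeric(0))
  tab$id <- seq_len(nrow(tab))
  truth <- structure(list(object_table = tab,
                          occupied = occupied,
                          pixel_size_um = spec$pixel_size_um),
                     class = "phantom_truth")
  list(image = image, truth = truth)
}

#' Specification of a 2-D neuron phantom
#'
#' A soma disk with curved neurites of requested arc lengths, optionally
#' terminated by elliptical growth-cone bulbs of requested area and
#' circularity; four channels (F-actin bulb-enriched, septin, tubulin
#' shaft-enriched, and a pSer9-GSK3-beta-like channel generated at a
#' configurable pixelwise correlation to septin).
#'
#' @param shape Field dimensions in pixels.
#' @param pixel_size_um Pixel size (default 0.108 um).
#' @param neurite_lengths_um Arc lengths of the neurites.
#' @param neurite_width_px Tube width of the neurites.
#' @param cone_area_um2 Growth-cone area per neurite (`NA` = flush tip,
#'   no bulb).
#' @param cone_circularity Target bulb circularity (sets the ellipse
#'   aspect; default 0.5).
#' @param ps9_rho Pixelwise correlation of the pS9 channel to septin.
#' @param intensity Amplitude of the neurite tube above background.
#' @param background_level,noise_sd Background and per-channel Gaussian
#'   noise.
#' @param seed Integer RNG seed.
#' @return Object of class `neuron_field_spec`.
#' @export
neuron_field_spec <- function(shape = c(420, 420), pixel_size_um = 0.108,
                              neurite_lengths_um = c(16, 10),
                              neurite_width_px = 7,
                              cone_area_um2 = c(12, NA),
                              cone_circularity = 0.5,
                              ps9_rho = 0.5, intensity = 150,
                              background_level = 50, noise_sd = 3,
                              seed = 1L) {
  stopifnot(length(neurite_lengths_um) >= 1, all(neurite_lengths_um > 0))
  if (length(cone_area_um2) == 1)
    cone_area_um2 <- rep(cone_area_um2, length(neurite_lengths_um))
  stopifnot(length(cone_area_um2) == length(neurite_lengths_um))
  structure(as.list(environment()), class = "neuron_field_spec")
}

# ellipse aspect k solving circularity c = 4k / (3(k+1) - sqrt((3k+1)(k+3)))^2
# (Ramanujan perimeter approximation), by root finding
.aspect_for_circularity <- function(circ) {
  f <- function(k) 4 * k / (3 * (k + 1) - sqrt((3 * k + 1) * (k + 3)))^2 - circ
  if (circ >= 1) return(1)
  stats::uniroot(f, c(1 + 1e-6, 50))$root
}

#' Generate a 2-D neuron phantom
#'
#' @param spec A [neuron_field_spec()].
#' @return List with `channels` (named list of matrices: `factin`,
#'   `sep9`, `tubulin`, `ps9`) and `truth` (class `phantom_truth`):
#'   `neurite_lengths_um`, per-cone `cone_table` (`area_um2`,
#'   `circularity`, `tip_x`, `tip_y`), `soma_center`, masks
#'   `neuron_mask`, `cone_mask`, `shaft_mask` and the generating
#'   `ps9_rho`.
#' @export
make_neuron_field_2d <- function(spec = neuron_field_spec()) {
  stopifnot(inherits(spec, "neuron_field_spec"))
  set.seed(spec$seed)
  d <- spec$shape
  px <- spec$pixel_size_um
  soma_r <- 14
  ctr <- d / 2
  tube <- matrix(0, d[1], d[2])       # neurite + soma amplitude map
  cone_mask <- matrix(FALSE, d[1], d[2])
  cones <- list()
  n <- length(spec$neurite_lengths_um)
  angles <- seq(0, 2 * pi, length.out = n + 1)[seq_len(n)] +
    runif(1, 0, 2 * pi / max(1, n))
  tube <- .draw_ellipse(tube, ctr, soma_r, soma_r, 0, spec$intensity)
  tips <- matrix(NA_real_, n, 2)
  # neurites are gentle circular arcs (constant small curvature): no
  # self-crossing, and tips/bulbs are kept inside the field and away
  # from other neurites by resampling
  margin <- 46
  arc_points <- function(angle, len_px) {
    for (try in 1:40) {
      kappa <- runif(1, -1, 1) * runif(1, 0, 0.004)
      dir0 <- angle + runif(1, -0.2, 0.2)
      n_steps <- ceiling(len_px / 3)
      th <- dir0 + kappa * 3 * (seq_len(n_steps) - 1)
      pts <- cbind(ctr[1] + (soma_r - 1) * cos(angle) + cumsum(3 * cos(th)),
                   ctr[2] + (soma_r - 1) * sin(angle) + cumsum(3 * sin(th)))
      pts <- rbind(ctr + (soma_r - 1) * c(cos(angle), sin(angle)), pts)
      if (all(pts > margin) && all(pts[, 1] < d[1] - margin) &&
          all(pts[, 2] < d[2] - margin)) return(pts)
    }
    stop("could not fit a neurite of that length in the field")
  }
  paths <- list()
  for (i in seq_len(n)) {
    len_px <- spec$neurite_lengths_um[i] / px
    for (try in 1:40) {
      pts <- arc_points(angles[i], len_px)
      clash <- FALSE
      if (length(paths) > 0) {
        a <- pts[-seq_len(min(4, nrow(pts) - 1)), , drop = FALSE]
        for (pp in paths) {
          b <- pp[-seq_len(min(4, nrow(pp) - 1)), , drop = FALSE]
          dm <- outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2
          if (min(dm) < (4 * spec$neurite_width_px)^2) { clash <- TRUE; break }
        }
      }
      if (!clash) break
    }
    if (clash) stop("could not place neurite ", i, " without collisions")
    paths[[i]] <- pts
    for (k in seq_len(nrow(pts) - 1))
      tube <- .draw_segment(tube, pts[k, ], pts[k + 1, ],
                            spec$neurite_width_px, spec$intensity)
    p <- pts[nrow(pts), ]
    dir <- p - pts[nrow(pts) - 1, ]
    dir <- dir / sqrt(sum(dir^2))
    tips[i, ] <- p
    if (!is.na(spec$cone_area_um2[i])) {
      area_px <- spec$cone_area_um2[i] / px^2
      k <- .aspect_for_circularity(spec$cone_circularity)
      b <- sqrt(area_px / (pi * k)); a <- k * b
      th <- atan2(dir[2], dir[1]) + pi / 2  # fan perpendicular to neurite
      cone_c <- p + dir * (b * 0.8)
      probe <- matrix(0, d[1], d[2])
      probe <- .draw_ellipse(probe, cone_c, a, b, th, 1)
      tube <- pmax(tube, probe * spec$intensity)
      cone_mask <- cone_mask | probe > 0
      cones[[length(cones) + 1]] <- data.frame(
        neurite = i, area_um2 = sum(probe > 0) * px^2,
        circularity = spec$cone_circularity,
        tip_x = p[1], tip_y = p[2])
    }
  }
  neuron_mask <- tube > 0
  shaft_mask <- neuron_mask & !cone_mask
  # channel construction: enrichment by compartment
  mk_chan <- function(weights_cone, weights_shaft) {
    amp <- matrix(0, d[1], d[2])
    amp[shaft_mask] <- weights_shaft * tube[shaft_mask]
    amp[cone_mask] <- weights_cone * tube[cone_mask]
    amp
  }
  blur2 <- function(m) matrix(.gauss_sep(.as_vol(m), c(1, 1, 1)), d[1], d[2])
  noise <- function() matrix(rnorm(prod(d), 0, spec$noise_sd), d[1], d[2])
  # septin: spatial texture inside the neuron (smoothed multiplicative)
  tex <- matrix(.gauss_sep(.as_vol(matrix(rnorm(prod(d)), d[1], d[2])),
                           c(2, 2, 1)), d[1], d[2])
  tex <- tex / stats::sd(tex)
  sep_amp <- mk_chan(1.0, 0.8) * (1 + 0.5 * pmax(-0.9, tex))
  factin <- pmax(blur2(mk_chan(1.5, 0.6)) + spec$background_level + noise(), 0)
  tubulin <- pmax(blur2(mk_chan(0.4, 1.2)) + spec$background_level + noise(), 0)
  sep9 <- pmax(blur2(sep_amp) + spec$background_level + noise(), 0)
  # pS9 channel: septin mixed with a noise field orthogonalized against
  # septin over the truth shaft, so the pixelwise correlation to septin
  # over the shaft equals ps9_rho exactly by construction
  eps <- matrix(.gauss_sep(.as_vol(matrix(rnorm(prod(d)), d[1], d[2])),
                           c(1, 1, 1)), d[1], d[2])
  sh <- neuron_mask & !cone_mask
  std_over <- function(x) (x - mean(x[sh])) / stats::sd(x[sh])
  s_std <- std_over(sep9)
  e_std <- std_over(eps)
  e_orth <- std_over(e_std - cor(e_std[sh], s_std[sh]) * s_std)
  rho <- spec$ps9_rho
  mix <- rho * s_std + sqrt(max(0, 1 - rho^2)) * e_orth
  ps9 <- spec$background_level + 40 * mix
  ps9 <- ps9 - min(ps9)  # keep non-negative without clamping (affine)
  cone_table <- if (length(cones) > 0) do.call(rbind, cones) else
    data.frame(neurite = integer(0), area_um2 = numeric(0),
               circularity = numeric(0), tip_x = numeric(0),
               tip_y = numeric(0))
  truth <- structure(list(
    neurite_lengths_um = spec$neurite_lengths_um,
    cone_table = cone_table, soma_center = ctr,
    neuron_mask = neuron_mask, cone_mask = cone_mask,
    shaft_mask = shaft_mask, ps9_rho = spec$ps9_rho,
    pixel_size_um = px), class = "phantom_truth")
  list(channels = list(factin = factin, sep9 = sep9, tubulin = tubulin,
                       ps9 = ps9),
       truth = truth)
}
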