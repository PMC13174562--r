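# Neuron compartment morphometry: neurite mask, growth-cone detection,
# shaft definition, per-compartment Pearson correlation, Cohen's d and
# the neurite polarity call.

#' Neurite mask from F-actin and septin channels
#'
#' Thresholds the composite (sum of per-channel min-max normalized images)
#' at 0.35 times its Otsu threshold and removes components smaller than
#' `min_component_px` (default 100 px). The scaled-down Otsu recovers thin
#' dim neurites that a full Otsu cut would lose.
#'
#' @param factin,sep9 Co-registered numeric 2-D matrices.
#' @param otsu_scale Threshold scale factor (default 0.35).
#' @param min_component_px Small-component removal (default 100).
#' @return Logical matrix; empty with a warning on a blank field.
#' @export
neurite_mask <- function(factin, sep9, otsu_scale = 0.35,
                         min_component_px = 100) {
  stopifnot(identical(dim(factin), dim(sep9)), length(dim(factin)) == 2)
  norm01 <- function(v) {
    lo <- min(v); hi <- max(v)
    if (hi - lo <= 0) return(array(0, dim(v)))
    (v - lo) / (hi - lo)
  }
  composite <- norm01(factin) + norm01(sep9)
  if (max(composite) <= 0) {
    warning("blank field: empty neurite mask")
    return(matrix(FALSE, nrow(factin), ncol(factin)))
  }
  thr <- otsu_scale * otsu_threshold(composite)
  mask <- composite > thr
  mask <- remove_small_components(mask, min_component_px, 26)
  out <- matrix(mask, nrow(factin), ncol(factin))
  if (!any(out)) warning("empty neurite mask after filtering")
  out
}


# remove short skeleton spurs: from each endpoint, walk along the
# skeleton; if a branch point is reached within max_len_px steps the
# walked branch is a spur and is deleted. Keeps genuine neurite tips.
.prune_spurs <- function(skmask, max_len_px = 12) {
  m <- .as_vol(skmask)
  repeat {
    nb <- .neighbor_counts(m)
    eps <- which(m & nb == 1, arr.ind = TRUE)
    removed_any <- FALSE
    for (i in seq_len(nrow(eps))) {
      path <- matrix(eps[i, ], 1, 3)
      cur <- eps[i, ]
      prev <- c(-1, -1, -1)
      is_spur <- FALSE
      for (step in seq_len(max_len_px)) {
        if (nb[cur[1], cur[2], cur[3]] >= 3) { is_spur <- TRUE; break }
        xs <- max(1, cur[1] - 1):min(dim(m)[1], cur[1] + 1)
        ys <- max(1, cur[2] - 1):min(dim(m)[2], cur[2] + 1)
        zs <- max(1, cur[3] - 1):min(dim(m)[3], cur[3] + 1)
        nxt <- NULL
        for (x in xs) for (y in ys) for (z in zs) {
          if (!m[x, y, z]) next
          if (all(c(x, y, z) == cur) || all(c(x, y, z) == prev)) next
          if (nrow(path) > 1 && any(apply(path, 1, function(r)
            all(r == c(x, y, z))))) next
          nxt <- c(x, y, z); break
        }
        if (is.null(nxt)) break
        prev <- cur
        cur <- nxt
        path <- rbind(path, cur)
      }
      if (is_spur) {
        # delete the walked pixels short of the branch point
        drop <- path[-nrow(path), , drop = FALSE]
        m[drop] <- FALSE
        removed_any <- TRUE
      }
    }
    if (!removed_any) break
  }
  m
}

# geometry used for pixel-unit 2-D work (1 px = 1000 nm so that skeleton
# "length_um" is in pixels)
.px_geom <- voxel_geometry(1000)

#' Detect growth cones at neurite tips
#'
#' Candidate bulbs are connected components of the mask's morphological
#' opening with a disk slightly wider than the median neurite half-width:
#' the opening erases the shaft, so only locally wide structures (bulbs,
#' varicosities, the soma) remain as candidates.
#' A candidate is retained when it contains a skeleton endpoint (it is
#' terminal), its area exceeds `min_area_um2` (5 um^2) and its
#' circularity `4*pi*A/P^2` is below `max_circularity` (0.7). Retained
#' regions are dilated by `dilate_px` (3 px) to recover labile membrane
#' edges.
#'
#' @param mask Logical 2-D neurite mask.
#' @param pixel_size_um Pixel size in micrometers.
#' @param min_area_um2,max_circularity,dilate_px Acceptance rules.
#' @return List of growth-cone regions; each has `pixels` (logical
#'   matrix, post-dilation), `core_pixels` (pre-dilation), `area_um2`,
#'   `circularity`, `tip` (endpoint coordinates). Empty list when none.
#' @export
detect_growth_cones <- function(mask, pixel_size_um, min_area_um2 = 5,
                                max_circularity = 0.7, dilate_px = 3) {
  stopifnot(length(dim(mask)) == 2, pixel_size_um > 0)
  if (!any(mask)) stop("empty mask")
  m <- .as_vol(mask)
  skel <- skeletonize_3d_lee(m, .px_geom)
  sk <- .prune_spurs(skel$mask, 12)
  nb <- .neighbor_counts(sk)
  endpoints <- which(sk & nb == 1, arr.ind = TRUE)
  # median neurite half-width from the distance transform at skeleton px
  d_px <- distance_to_mask(!m, .px_geom) / 1000
  half_w <- median(d_px[skel$mask])
  if (!is.finite(half_w) || half_w < 1) half_w <- 1
  # opening with a disk slightly wider than the median neurite
  # half-width erases the shaft; only locally wide structures - bulbs,
  # varicosities and the soma - survive and become candidates (the
  # terminality test below separates bulbs from the rest)
  open_r <- (half_w + 2) * 1000  # nm under the pixel geometry
  opened <- binary_dilate(binary_erode(m, open_r, .px_geom), open_r, .px_geom)
  lab <- label_components(opened & m, 26)
  cones <- list()
  if (max(lab) > 0 && nrow(endpoints) > 0) {
    for (cid in seq_len(max(lab))) {
      comp <- lab == cid
      # terminal: contains (or touches within 2 px) a skeleton endpoint
      ep_in <- vapply(seq_len(nrow(endpoints)), function(i) {
        e <- endpoints[i, ]
        xs <- max(1, e[1] - 2):min(dim(comp)[1], e[1] + 2)
        ys <- max(1, e[2] - 2):min(dim(comp)[2], e[2] + 2)
        any(comp[xs, ys, e[3]])
      }, logical(1))
      if (!any(ep_in)) next
      comp2d <- matrix(comp, dim(comp)[1], dim(comp)[2])
      area_um2 <- sum(comp2d) * pixel_size_um^2
      circ <- .circularity(comp2d)
      if (area_um2 <= min_area_um2 || !is.finite(circ) ||
          circ >= max_circularity) next
      dil <- binary_dilate(comp, dilate_px * 1000, .px_geom)
      tip <- endpoints[which(ep_in)[1], 1:2]
      cones[[length(cones) + 1]] <-
        list(pixels = matrix(dil, dim(dil)[1], dim(dil)[2]),
             core_pixels = comp2d, area_um2 = area_um2,
             circularity = circ, tip = tip)
    }
  }
  cones
}

#' Axon shaft region proximal to a growth cone
#'
#' From each cone's skeleton endpoint, walks the neurite skeleton
#' proximally for `reach_um` of geodesic length, stopping at branch
#' points; the walked centerline is dilated to the local neurite width
#' and cone pixels are removed, yielding the elongated shaft region.
#'
#' @param mask Logical 2-D neurite mask.
#' @param cones Output of [detect_growth_cones()] (at least one cone).
#' @param pixel_size_um Pixel size in micrometers.
#' @param reach_um Proximal reach along the skeleton (default 20 um).
#' @return Logical matrix (union over cones); cones with no skeleton
#'   connection are skipped with a warning.
#' @export
shaft_region <- function(mask, cones, pixel_size_um, reach_um = 20) {
  stopifnot(length(cones) >= 1, pixel_size_um > 0)
  m <- .as_vol(mask)
  skel <- skeletonize_3d_lee(m, .px_geom)
  sk <- .prune_spurs(skel$mask, 12)
  nb <- .neighbor_counts(sk)
  d_px <- distance_to_mask(!m, .px_geom) / 1000
  half_w <- max(1, median(d_px[sk]))
  reach_px <- reach_um / pixel_size_um
  cone_union <- Reduce(`|`, lapply(cones, function(cn) cn$pixels))
  sk2 <- matrix(sk, dim(m)[1], dim(m)[2])
  nb2 <- matrix(nb, dim(m)[1], dim(m)[2])
  shaft <- matrix(FALSE, dim(m)[1], dim(m)[2])
  for (cn in cones) {
    # start: the skeleton pixel just outside the cone, at the junction
    # (minimal distance to the cone region)
    cand <- which(sk2 & !cn$pixels, arr.ind = TRUE)
    if (nrow(cand) == 0) { warning("cone with no skeleton connection"); next }
    dcone <- matrix(distance_to_mask(cn$pixels, .px_geom) / 1000,
                    nrow(sk2), ncol(sk2))
    dd <- dcone[cand[, 1:2]]
    if (min(dd) > 6) { warning("cone with no skeleton connection"); next }
    walk_from <- function(start) {
      cur <- start
      visited <- matrix(FALSE, nrow(sk2), ncol(sk2))
      visited[cur[1], cur[2]] <- TRUE
      walked <- 0
      path <- matrix(cur, 1, 2)
      while (walked < reach_px) {
        if (nb2[cur[1], cur[2]] >= 3) break  # branch point: stop
        xs <- max(1, cur[1] - 1):min(nrow(sk2), cur[1] + 1)
        ys <- max(1, cur[2] - 1):min(ncol(sk2), cur[2] + 1)
        nxt <- NULL
        best <- -Inf
        for (x in xs) for (y in ys) {
          if (!sk2[x, y] || visited[x, y] || (x == cur[1] && y == cur[2]))
            next
          # walk proximally: prefer the neighbor farther from the cone
          if (dcone[x, y] > best) { best <- dcone[x, y]; nxt <- c(x, y) }
        }
        if (is.null(nxt)) break
        walked <- walked + sqrt(sum((nxt - cur)^2))
        visited[nxt[1], nxt[2]] <- TRUE
        path <- rbind(path, nxt)
        cur <- nxt
      }
      list(path = path, walked = walked)
    }
    # several skeleton pixels can abut the cone (e.g., both bulb flanks);
    # walk from the nearest few and keep the longest proximal run
    starts <- cand[dd <= 6, , drop = FALSE]
    starts <- starts[order(dcone[starts[, 1:2]])[
      seq_len(min(4, nrow(starts)))], , drop = FALSE]
    best_walk <- NULL
    for (si in seq_len(nrow(starts))) {
      w <- walk_from(starts[si, 1:2])
      if (is.null(best_walk) || w$walked > best_walk$walked) best_walk <- w
    }
    path <- best_walk$path
    # dilate the walked centerline to the local neurite width
    cl <- matrix(FALSE, nrow(sk2), ncol(sk2))
    cl[path] <- TRUE
    tube <- binary_dilate(cl, (half_w + 0.5) * 1000, .px_geom)
    shaft <- shaft | (matrix(tube, nrow(sk2), ncol(sk2)) &
                        matrix(m, nrow(sk2), ncol(sk2)))
  }
  shaft & !cone_union
}

#' Pearson correlation within a compartment
#'
#' Subtracts per-channel backgrounds (clamped at zero) and computes the
#' standard Pearson correlation over the region pixels. Background
#' defaults to the per-channel median outside the neurite mask.
#'
#' @param chan_a,chan_b Numeric 2-D matrices.
#' @param region Logical matrix (>= 10 pixels).
#' @param bg_a,bg_b Scalar backgrounds; if `NULL` and `neurite` is given,
#'   the median outside the neurite mask is used, else 0.
#' @param neurite Optional logical neurite mask for background estimation.
#' @param clamp Clamp background-subtracted intensities at zero (default
#'   `TRUE`; set `FALSE` to correlate signed residuals).
#' @param compartment,fov_id,pair_name Labels carried into the record.
#' @return Object of class `correlation_record`: `pearson_r`, `n_pixels`,
#'   labels; `pearson_r = NA` with `reason` on zero variance.
#' @export
compartment_pearson <- function(chan_a, chan_b, region, bg_a = NULL,
                                bg_b = NULL, neurite = NULL, clamp = TRUE,
                                compartment = NA_character_,
                                fov_id = NA_character_,
                                pair_name = NA_character_) {
  stopifnot(identical(dim(chan_a), dim(chan_b)),
            identical(dim(chan_a), dim(region)))
  n <- sum(region)
  if (n < 10) stop("region must contain at least 10 pixels")
  default_bg <- function(ch) {
    if (!is.null(neurite) && any(!neurite)) median(ch[!neurite]) else 0
  }
  if (is.null(bg_a)) bg_a <- default_bg(chan_a)
  if (is.null(bg_b)) bg_b <- default_bg(chan_b)
  a <- chan_a[region] - bg_a
  b <- chan_b[region] - bg_b
  if (clamp) { a <- pmax(0, a); b <- pmax(0, b) }
  rec <- list(fov_id = fov_id, compartment = compartment, pair = pair_name,
              pearson_r = NA_real_, n_pixels = as.integer(n),
              reason = NA_character_)
  if (sd(a) == 0 || sd(b) == 0) {
    rec$reason <- "zero variance in a channel over the region"
  } else {
    rec$pearson_r <- cor(a, b)
  }
  structure(rec, class = "correlation_record")
}

#' @export
print.correlation_record <- function(x, ...) {
  cat(sprintf("correlation_record [%s/%s/%s]: r = %s (n = %d)\n",
              x$fov_id, x$compartment, x$pair,
              ifelse(is.na(x$pearson_r), "NA", sprintf("%.3f", x$pearson_r)),
              x$n_pixels))
  invisible(x)
}

#' Cohen's d effect size
#'
#' `d = (mean(b) - mean(a)) / pooled SD` with the n-weighted pooled
#' variance `((n_a - 1) s_a^2 + (n_b - 1) s_b^2) / (n_a + n_b - 2)`.
#'
#' @param group_a,group_b Numeric samples, each of length >= 2.
#' @return Object of class `effect_size`: `cohen_d`, `group_means`,
#'   `group_sds`, `group_ns`; `cohen_d = NA` when the pooled SD is zero.
#' @export
cohens_d <- function(group_a, group_b) {
  na <- length(group_a); nb <- length(group_b)
  stopifnot(na >= 2, nb >= 2)
  sa <- sd(group_a); sb <- sd(group_b)
  pooled <- sqrt(((na - 1) * sa^2 + (nb - 1) * sb^2) / (na + nb - 2))
  d <- if (pooled == 0) NA_real_ else (mean(group_b) - mean(group_a)) / pooled
  structure(list(cohen_d = d,
                 group_means = c(mean(group_a), mean(group_b)),
                 group_sds = c(sa, sb), group_ns = c(na, nb)),
            class = "effect_size")
}

#' @export
print.effect_size <- function(x, ...) {
  cat(sprintf("effect_size: Cohen's d = %s (n = %d, %d)\n",
              ifelse(is.na(x$cohen_d), "NA", sprintf("%.3f", x$cohen_d)),
              x$group_ns[1], x$group_ns[2]))
  invisible(x)
}

#' Classify neurite polarity
#'
#' A neuron is *polarized* when it has a single neurite, or when its
#' longest neurite is at least twice the length of the second longest
#' ("at least twice" is inclusive: exactly 2x counts as polarized);
#' otherwise it is *multipolar*. The rule is a pure length ratio and is
#' invariant to units.
#'
#' @param neurite_lengths_um Numeric vector of traced neurite lengths
#'   (non-empty, non-negative).
#' @return Object of class `polarity_call`: `neurite_lengths_um` (sorted
#'   descending) and `label` in `{"polarized", "multipolar"}`.
#' @export
classify_polarity <- function(neurite_lengths_um) {
  if (length(neurite_lengths_um) == 0) stop("no neurite lengths given")
  if (any(neurite_lengths_um < 0)) stop("lengths must be non-negative")
  s <- sort(neurite_lengths_um, decreasing = TRUE)
  label <- if (length(s) == 1 || s[1] >= 2 * s[2]) "polarized" else "multipolar"
  structure(list(neurite_lengths_um = s, label = label),
            class = "polarity_call")
}

#' @export
print.polarity_call <- function(x, ...) {
  cat(sprintf("polarity_call: %s (lengths %s um)\n", x$label,
              paste(sprintf("%.1f", x$neurite_lengths_um), collapse = ", ")))
  invisible(x)
}
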