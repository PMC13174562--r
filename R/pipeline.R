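# Configuration, stack IO, the end-to-end 3-D colocalization driver and
# results writing.

#' Default pipeline configuration
#'
#' A nested list holding every tunable parameter of the pipeline with its
#' default: voxel geometry, masking, bleed bounds, ridge parameters, the
#' skeleton-overlap dilation radius (2 voxels), minimum skeleton length
#' (1 um), and the overlap direction (`"sep_in_mt"`, the septin-skeleton-
#' in-MT-mask fraction; `"mt_in_sep"` measures the reverse).
#'
#' @return Named list of class `pipeline_config`.
#' @export
default_config <- function() {
  structure(list(
    voxel = list(dx_nm = 108, dy_nm = 108, dz_nm = 200),
    masking = unclass(masking_params()),
    bleed = c(unclass(bleed_bounds()), list(min_voxels = 50, floor_k = 2)),
    ridges = unclass(ridge_params()),
    coloc = list(dilation_vox = 2, min_skeleton_length_um = 1,
                 overlap_direction = "sep_in_mt"),
    bundles = list(bundle_width_px = 12, min_aspect = 3, min_length_um = 10,
                   min_object_px = 15),
    neurons = list(otsu_scale = 0.35, min_component_px = 100,
                   min_area_um2 = 5, max_circularity = 0.7, dilate_px = 3,
                   reach_um = 20)
  ), class = "pipeline_config")
}

#' Load / save a pipeline configuration (YAML)
#'
#' Unknown keys are rejected; missing keys take their defaults.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
load_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_config()
  for (section in names(user)) {
    if (!section %in% names(cfg))
      stop("unknown config section: ", section)
    for (key in names(user[[section]])) {
      if (!key %in% names(cfg[[section]]))
        stop("unknown config key: ", section, "$", key)
      cfg[[section]][[key]] <- user[[section]][[key]]
    }
  }
  cfg
}

#' @rdname load_config
#' @param config A `pipeline_config` to write.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Hash of a configuration (FNV-1a over its canonical deparse)
#'
#' Changes iff any config value changes; stamped on every results row so
#' each metric is traceable to the exact parameters that produced it.
#'
#' @param config A `pipeline_config` (or any R list).
#' @return 8-hex-digit character scalar.
#' @export
config_hash <- function(config) {
  s <- paste(deparse(config, control = c("keepNA", "keepInteger")),
             collapse = "")
  bytes <- utf8ToInt(s)
  h <- 2166136261
  for (b in bytes) {
    # xor affects only the low byte; keep h in doubles (32-bit range)
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b %% 256))
    # FNV prime 16777619, in 32-bit modular arithmetic via doubles
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%08x", as.integer(h %% 2147483648))
}

#' Read a two-channel stack from multi-page TIFF
#'
#' Pages are interpreted as z-planes of interleaved channels
#' (`c1 z1, c2 z1, c1 z2, ...`) or as blocks per channel, controlled by
#' `interleaved`. Voxel sizes come from the config (TIFF rarely carries
#' calibrated 3-D metadata).
#'
#' @param path TIFF file path.
#' @param channel_map Named integer vector mapping channel names to
#'   indices, e.g. `c(SEP = 1, MT = 2)`.
#' @param geometry A [voxel_geometry()] supplying voxel sizes.
#' @param n_channels Number of channels in the file (default 2).
#' @param interleaved Channel-plane interleaving (default `TRUE`).
#' @return A [field_pair()].
#' @export
load_stack <- function(path, channel_map = c(SEP = 1, MT = 2),
                       geometry = voxel_geometry(108, 108, 200),
                       n_channels = 2, interleaved = TRUE) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  n_pages <- length(pages)
  if (n_pages %% n_channels != 0)
    stop("page count ", n_pages, " is not a multiple of n_channels")
  if (any(channel_map > n_channels))
    stop("channel map names channel ", max(channel_map),
         " but the file has ", n_channels)
  nz <- n_pages / n_channels
  grab <- function(ci) {
    idx <- if (interleaved) seq(ci, n_pages, by = n_channels)
    else seq((ci - 1) * nz + 1, ci * nz)
    planes <- pages[idx]
    # TIFF pages are row-major (y, x); transpose to (x, y)
    arr <- array(0, c(ncol(planes[[1]]), nrow(planes[[1]]), nz))
    for (k in seq_len(nz)) arr[, , k] <- t(planes[[k]])
    arr
  }
  field_pair(channel_stack(grab(channel_map[["SEP"]]), geometry, "SEP"),
             channel_stack(grab(channel_map[["MT"]]), geometry, "MT"))
}

#' Write a stack (or mask) as multi-page TIFF
#'
#' Float pages for intensities, 8-bit 0/255 for logical masks.
#'
#' @param x 3-D array (numeric or logical) or `channel_stack`.
#' @param path Output path.
#' @export
write_stack <- function(x, path) {
  v <- .values(if (is.logical(x)) x * 1 else x)
  if (max(v) > 0 && all(v %in% c(0, 1))) {
    pages <- lapply(seq_len(dim(v)[3]), function(z) t(v[, , z]))
    tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  } else {
    scale <- max(v, 1)
    pages <- lapply(seq_len(dim(v)[3]), function(z) t(v[, , z]) / scale)
    tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  }
  invisible(path)
}

#' End-to-end 3-D septin-microtubule colocalization
#'
#' For one two-channel stack: cell mask, nucleus/exNuc, background and
#' bleed-slope estimation, bleed correction (when accepted), septin white
#' top-hat and microtubule Gaussian high-pass, 3-D Frangi vesselness for
#' both channels, hysteresis thresholding within the cell (quantile
#' levels), closing, restriction to exNuc, skeletonization, minimum-
#' length pruning, then the skeleton-overlap fraction and the Manders
#' coefficient. Missing values propagate as flagged columns, never as
#' errors.
#'
#' @param pair A [field_pair()].
#' @param config A `pipeline_config` (see [default_config()]).
#' @param cell_id Identifier stamped on the result row.
#' @return Object of class `coloc3d_result`: a one-row data.frame
#'   `metrics` plus intermediate objects (`masks`, `bleed`, `skeletons`,
#'   `mt_mask`) for audit.
#' @export
run_coloc3d <- function(pair, config = default_config(), cell_id = "cell1") {
  stopifnot(inherits(pair, "field_pair"))
  g <- pair$sep$geometry
  mp <- do.call(masking_params, config$masking)
  cell <- compute_cell_mask(pair, mp)
  flag <- NA_character_
  if (!any(cell)) {
    metrics <- data.frame(cell_id = cell_id, alpha = NA_real_,
                          alpha_status = "no_cell",
                          skeleton_overlap_fraction = NA_real_,
                          manders = NA_real_, n_skeleton_voxels = 0L,
                          cell_volume_um3 = 0, nucleus_volume_um3 = 0,
                          exnuc_volume_um3 = 0,
                          flag = "empty cell mask",
                          config_hash = config_hash(config))
    return(structure(list(metrics = metrics), class = "coloc3d_result"))
  }
  masks <- compute_nucleus_mask(pair, cell, mp)
  bg <- estimate_background(pair, cell)
  bounds <- bleed_bounds(config$bleed$cap, config$bleed$reject_above)
  est <- estimate_bleed_slope(pair, masks$exnuc, bg, bounds,
                              min_voxels = config$bleed$min_voxels,
                              floor_k = config$bleed$floor_k)
  sep_corr <- if (est$status %in% c("accepted", "capped")) {
    correct_bleed(pair, est)
  } else {
    flag <- paste("bleed estimate rejected:", est$reason)
    pair$sep$values
  }
  rp <- do.call(ridge_params, config$ridges)
  sep_pre <- white_tophat_3d(sep_corr, rp$tophat_radii_nm,
                             geometry = g)
  mt_pre <- pmax(gaussian_highpass(pair$mt$values, rp$highpass_sigma_nm,
                                   geometry = g), 0)
  seg_channel <- function(pre) {
    resp <- frangi_3d(pre, rp, geometry = g)
    in_cell <- resp[masks$cell]
    # hysteresis levels are quantiles of the active response support
    # (above 2 percent of the in-cell maximum): quantiles of the raw
    # in-cell response would scale with how much of the cell is
    # filamentous and segment faint texture in sparse fields
    support <- in_cell[in_cell > 0.02 * max(in_cell)]
    if (length(support) < 10) support <- in_cell
    hi <- quantile(support, rp$hysteresis_high_q)
    lo <- quantile(support, rp$hysteresis_low_q)
    m <- hysteresis_mask(resp, lo, hi, within = masks$cell)
    if (any(m)) m <- binary_close(m, g$dx, g)  # 1-voxel lateral gap repair
    m & masks$exnuc
  }
  sep_mask <- seg_channel(sep_pre)
  mt_mask <- seg_channel(mt_pre)
  min_len <- config$coloc$min_skeleton_length_um
  sep_skel <- prune_skeleton(skeletonize_3d_lee(sep_mask, g), min_len)
  mt_skel <- prune_skeleton(skeletonize_3d_lee(mt_mask, g), min_len)
  ov <- if (identical(config$coloc$overlap_direction, "mt_in_sep")) {
    skeleton_overlap_fraction(mt_skel, sep_mask, config$coloc$dilation_vox)
  } else {
    skeleton_overlap_fraction(sep_skel, mt_mask, config$coloc$dilation_vox)
  }
  man <- manders_coefficient(sep_corr, mt_mask, masks$exnuc)
  if (is.na(ov$fraction) && is.na(flag)) flag <- ov$reason
  voxel_um3 <- g$dx * g$dy * g$dz / 1e9
  metrics <- data.frame(
    cell_id = cell_id, alpha = est$alpha, alpha_status = est$status,
    skeleton_overlap_fraction = ov$fraction,
    manders = as.numeric(man),
    n_skeleton_voxels = ov$n_skeleton_voxels,
    cell_volume_um3 = sum(masks$cell) * voxel_um3,
    nucleus_volume_um3 = sum(masks$nucleus) * voxel_um3,
    exnuc_volume_um3 = sum(masks$exnuc) * voxel_um3,
    flag = flag, config_hash = config_hash(config))
  structure(list(metrics = metrics, masks = masks, bleed = est,
                 sep_skeleton = sep_skel, mt_skeleton = mt_skel,
                 sep_mask = sep_mask, mt_mask = mt_mask),
            class = "coloc3d_result")
}

#' @export
print.coloc3d_result <- function(x, ...) {
  m <- x$metrics
  cat(sprintf("coloc3d_result [%s]\n", m$cell_id))
  cat(sprintf("  alpha: %s (%s)\n",
              ifelse(is.na(m$alpha), "NA", sprintf("%.4f", m$alpha)),
              m$alpha_status))
  cat(sprintf("  skeleton-overlap fraction: %s\n",
              ifelse(is.na(m$skeleton_overlap_fraction), "NA",
                     sprintf("%.3f", m$skeleton_overlap_fraction))))
  cat(sprintf("  Manders coefficient: %s\n",
              ifelse(is.na(m$manders), "NA", sprintf("%.3f", m$manders))))
  cat(sprintf("  volumes (um^3): cell %.1f, nucleus %.1f, exNuc %.1f\n",
              m$cell_volume_um3, m$nucleus_volume_um3, m$exnuc_volume_um3))
  invisible(x)
}

#' Write a results table with its configuration sidecar
#'
#' CSV with a stable column order; the config hash is written to
#' `<path>.confighash` so every output is traceable.
#'
#' @param table data.frame (e.g., rbind of `coloc3d_result$metrics`).
#' @param path Output CSV path.
#' @param config The `pipeline_config` used (for the sidecar).
#' @export
write_results <- function(table, path, config = default_config()) {
  write.csv(table, path, row.names = FALSE)
  writeLines(config_hash(config), paste0(path, ".confighash"))
  invisible(path)
}
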