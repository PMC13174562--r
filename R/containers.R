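#' Single-channel intensity stack
#'
#' A non-negative intensity grid (2-D or 3-D) together with its voxel
#' geometry and a channel label.
#'
#' @param values Numeric matrix or 3-D array of non-negative intensities.
#' @param geometry A [voxel_geometry()].
#' @param label Channel name, one of `"SEP"`, `"MT"` or `"other"`.
#' @return Object of class `channel_stack`.
#' @export
channel_stack <- function(values, geometry = voxel_geometry(),
                          label = c("other", "SEP", "MT")) {
  label <- match.arg(label)
  values <- .as_vol(values)
  .check_finite_nonneg(values)
  stopifnot(inherits(geometry, "voxel_geometry"))
  structure(list(values = values, geometry = geometry, label = label),
            class = "channel_stack")
}

#' @export
print.channel_stack <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("channel_stack '%s': %d x %d x %d voxels, range [%g, %g]\n",
              x$label, d[1], d[2], d[3], min(x$values), max(x$values)))
  print(x$geometry)
  invisible(x)
}

#' Two co-registered channels (septin + cytoskeleton)
#'
#' @param sep `channel_stack` for the septin channel.
#' @param mt `channel_stack` for the cytoskeleton (microtubule) channel.
#' @return Object of class `field_pair`.
#' @export
field_pair <- function(sep, mt) {
  stopifnot(inherits(sep, "channel_stack"), inherits(mt, "channel_stack"))
  if (!identical(dim(sep$values), dim(mt$values)))
    stop("channels must share the same grid shape")
  if (!isTRUE(all.equal(unclass(sep$geometry), unclass(mt$geometry))))
    stop("channels must share the same voxel geometry")
  structure(list(sep = sep, mt = mt), class = "field_pair")
}

#' @export
print.field_pair <- function(x, ...) {
  d <- dim(x$sep$values)
  cat(sprintf("field_pair: %d x %d x %d voxels\n", d[1], d[2], d[3]))
  print(x$sep$geometry)
  invisible(x)
}

# internal: accept channel_stack or bare array, return the array
.values <- function(x) if (inherits(x, "channel_stack")) x$values else .as_vol(x)
.geom <- function(x, geometry = NULL) {
  if (inherits(x, "channel_stack")) x$geometry
  else if (!is.null(geometry)) geometry
  else voxel_geometry()
}
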