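#' Multi-channel image scene
#'
#' The universal input container for all pipelines: a set of equally sized
#' 2D (or 2D+time) intensity rasters with physical pixel size. Coordinates
#' are 0-based and row-major; a pixel covers `pixel_size_um^2` square
#' micrometers. Intensities must be finite and non-negative.
#'
#' @param channels named list of numeric matrices (2D) or 3D arrays
#'   (`height x width x frames`, time series). All entries must share
#'   identical dimensions.
#' @param pixel_size_um micrometers per pixel, a single value `> 0`.
#' @param frame_interval_s seconds per frame for time series (`> 0`), or
#'   `NA` for single time points.
#' @return an object of class `ImageScene`.
#' @export
image_scene <- function(channels, pixel_size_um, frame_interval_s = NA_real_) {
  if (!is.list(channels) || length(channels) == 0L ||
      is.null(names(channels)) || any(!nzchar(names(channels)))) {
    stop("`channels` must be a non-empty named list of matrices/arrays")
  }
  if (anyDuplicated(names(channels))) stop("channel names must be unique")
  dims <- lapply(channels, dim)
  if (any(vapply(dims, is.null, logical(1)))) stop("channels must be matrices or arrays")
  d0 <- dims[[1]]
  for (d in dims) {
    if (length(d) != length(d0) || any(d != d0)) {
      stop("all channels must share identical dimensions")
    }
  }
  if (!(length(d0) %in% c(2L, 3L))) stop("channels must be 2D or 2D+time (3D)")
  for (nm in names(channels)) {
    ch <- channels[[nm]]
    if (!all(is.finite(ch))) stop("channel '", nm, "' contains non-finite pixels")
    if (any(ch < 0)) stop("channel '", nm, "' contains negative intensities")
    storage.mode(channels[[nm]]) <- "double"
  }
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0) {
    stop("`pixel_size_um` must be a single positive number")
  }
  if (length(d0) == 3L) {
    if (is.na(frame_interval_s) || frame_interval_s <= 0) {
      stop("time series require `frame_interval_s` > 0")
    }
  }
  structure(
    list(channels = channels,
         channel_names = names(channels),
         pixel_size_um = as.numeric(pixel_size_um),
         frame_interval_s = as.numeric(frame_interval_s)),
    class = "ImageScene"
  )
}

#' @export
print.ImageScene <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat("ImageScene:", paste(d, collapse = " x "),
      "| channels:", paste(x$channel_names, collapse = ", "),
      "| pixel:", x$pixel_size_um, "um\n")
  invisible(x)
}


# internal constructor for generators whose output is valid by
# construction (skips the per-pixel checks of image_scene)
.image_scene_fast <- function(channels, pixel_size_um,
                              frame_interval_s = NA_real_) {
  structure(list(channels = channels, channel_names = names(channels),
                 pixel_size_um = as.numeric(pixel_size_um),
                 frame_interval_s = as.numeric(frame_interval_s)),
            class = "ImageScene")
}

#' Extract one channel from a scene
#'
#' @param scene an [image_scene()].
#' @param channel channel name.
#' @param frame frame index for time series (default first).
#' @return numeric matrix.
#' @export
scene_channel <- function(scene, channel, frame = 1L) {
  stopifnot(inherits(scene, "ImageScene"))
  if (!channel %in% scene$channel_names) {
    stop("channel '", channel, "' not present (have: ",
         paste(scene$channel_names, collapse = ", "), ")")
  }
  ch <- scene$channels[[channel]]
  if (length(dim(ch)) == 3L) ch <- ch[, , frame] else ch
  ch
}

#' Integer label mask
#'
#' A raster of region labels: 0 is background, `k > 0` identifies region
#' `k`. `region_ids` is always the sorted set of nonzero labels present.
#'
#' @param labels integer matrix.
#' @return an object of class `LabelMask`.
#' @export
label_mask <- function(labels) {
  if (!is.matrix(labels)) stop("`labels` must be a matrix")
  storage.mode(labels) <- "integer"
  if (any(is.na(labels)) || any(labels < 0L)) stop("labels must be non-negative integers")
  ids <- sort(unique(labels[labels > 0L]))
  structure(list(labels = labels, region_ids = as.integer(ids)), class = "LabelMask")
}

#' @export
print.LabelMask <- function(x, ...) {
  cat("LabelMask:", paste(dim(x$labels), collapse = " x "),
      "|", length(x$region_ids), "regions\n")
  invisible(x)
}

#' Number of regions in a label mask
#' @param mask a [label_mask()].
#' @return integer count.
#' @export
n_regions <- function(mask) {
  stopifnot(inherits(mask, "LabelMask"))
  length(mask$region_ids)
}
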