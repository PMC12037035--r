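# Minimal baseline TIFF codec (little-endian, uncompressed, grayscale).
# The package writes 64-bit float scenes and 16-bit label masks and reads
# back what it writes plus plain single-sample uncompressed TIFFs from
# other tools. Scene metadata (channel names, pixel size, frame interval)
# travels in the ImageDescription tag as JSON; an OME-XML PhysicalSizeX
# attribute is honored on read.

.tiff_type_size <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 4L, `5` = 8L,
                     `6` = 1L, `7` = 1L, `8` = 2L, `9` = 4L, `10` = 8L,
                     `11` = 4L, `12` = 8L)

.tiff_write_pages <- function(pages, path, sample_format, bits, description) {
  stopifnot(sample_format %in% c(1L, 3L), length(pages) >= 1L)
  bytes_pp <- bits %/% 8L
  desc_raw <- c(charToRaw(description), as.raw(0L))
  if (length(desc_raw) %% 2L == 1L) desc_raw <- c(desc_raw, as.raw(0L))
  desc_off <- 8L
  data_off <- desc_off + length(desc_raw)
  sizes <- vapply(pages, function(p) length(p) * bytes_pp, numeric(1))
  offs <- data_off + cumsum(c(0, sizes[-length(sizes)]))
  ifd0 <- data_off + sum(sizes)
  if (ifd0 %% 2L == 1L) ifd0 <- ifd0 + 1L
  n_entries <- function(i) if (i == 1L) 11L else 10L
  ifd_size <- function(i) 2L + 12L * n_entries(i) + 4L
  ifd_offs <- ifd0 + cumsum(c(0, vapply(seq_along(pages)[-length(pages)],
                                        ifd_size, numeric(1))))
  con <- file(path, "wb")
  on.exit(close(con))
  w2 <- function(x) writeBin(as.integer(x), con, size = 2L, endian = "little")
  w4 <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  writeBin(charToRaw("II"), con)
  w2(42L)
  w4(ifd_offs[1])
  writeBin(desc_raw, con)
  for (i in seq_along(pages)) {
    v <- as.vector(t(pages[[i]]))
    if (sample_format == 3L) {
      writeBin(as.numeric(v), con, size = bytes_pp, endian = "little")
    } else {
      v <- as.integer(v)
      v[v > 32767L] <- v[v > 32767L] - 65536L  # wrap to signed for writeBin
      writeBin(v, con, size = 2L, endian = "little")
    }
  }
  if ((data_off + sum(sizes)) %% 2L == 1L) writeBin(as.raw(0L), con)
  ent_short <- function(tag, val) { w2(tag); w2(3L); w4(1L); w2(val); w2(0L) }
  ent_long <- function(tag, val) { w2(tag); w2(4L); w4(1L); w4(val) }
  for (i in seq_along(pages)) {
    h <- nrow(pages[[i]]); w <- ncol(pages[[i]])
    w2(n_entries(i))
    ent_long(256L, w)
    ent_long(257L, h)
    ent_short(258L, bits)
    ent_short(259L, 1L)
    ent_short(262L, 1L)
    if (i == 1L) { w2(270L); w2(2L); w4(length(desc_raw)); w4(desc_off) }
    ent_long(273L, offs[i])
    ent_short(277L, 1L)
    ent_long(278L, h)
    ent_long(279L, sizes[i])
    ent_short(339L, sample_format)
    w4(if (i < length(pages)) ifd_offs[i + 1L] else 0L)
  }
  invisible(path)
}

.tiff_read_pages <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 8L) stop("not a TIFF file: ", path)
  bo <- rawToChar(raw[1:2])
  endian <- if (bo == "II") "little" else if (bo == "MM") "big" else
    stop("not a TIFF file: ", path)
  rd <- function(off, n, size, what = "integer", signed = TRUE) {
    readBin(raw[(off + 1L):(off + n * size)], what, n = n, size = size,
            endian = endian, signed = signed)
  }
  if (rd(2L, 1L, 2L, signed = FALSE) != 42L) stop("not a TIFF file: ", path)
  ifd <- rd(4L, 1L, 4L)
  pages <- list()
  description <- NULL
  while (ifd > 0L) {
    n <- rd(ifd, 1L, 2L, signed = FALSE)
    tags <- list()
    for (i in seq_len(n)) {
      e <- ifd + 2L + (i - 1L) * 12L
      tag <- rd(e, 1L, 2L, signed = FALSE)
      typ <- rd(e + 2L, 1L, 2L, signed = FALSE)
      cnt <- rd(e + 4L, 1L, 4L)
      sz <- .tiff_type_size[as.character(typ)]
      if (is.na(sz)) next
      total <- as.numeric(sz) * cnt
      voff <- if (total <= 4L) e + 8L else rd(e + 8L, 1L, 4L)
      val <- switch(as.character(typ),
        `2` = rawToChar(raw[(voff + 1L):(voff + cnt)] [
                raw[(voff + 1L):(voff + cnt)] != as.raw(0L)]),
        `3` = rd(voff, cnt, 2L, signed = FALSE),
        `4` = rd(voff, cnt, 4L),
        `11` = rd(voff, cnt, 4L, what = "numeric"),
        `12` = rd(voff, cnt, 8L, what = "numeric"),
        NULL)
      if (!is.null(val)) tags[[as.character(tag)]] <- val
    }
    need <- c("256", "257", "273", "279")
    if (!all(need %in% names(tags))) stop("unsupported TIFF: missing required tags")
    if (!is.null(tags[["259"]]) && tags[["259"]] != 1L) {
      stop("unsupported TIFF: compressed data")
    }
    w <- tags[["256"]]; h <- tags[["257"]]
    bits <- if (is.null(tags[["258"]])) 1L else tags[["258"]][1]
    fmt <- if (is.null(tags[["339"]])) 1L else tags[["339"]][1]
    if (!is.null(tags[["277"]]) && tags[["277"]] != 1L) {
      stop("unsupported TIFF: multi-sample pixels")
    }
    offs <- tags[["273"]]; cnts <- tags[["279"]]
    buf <- raw(0)
    for (s in seq_along(offs)) {
      buf <- c(buf, raw[(offs[s] + 1L):(offs[s] + cnts[s])])
    }
    vals <- if (fmt == 3L) {
      readBin(buf, "numeric", n = w * h, size = bits %/% 8L, endian = endian)
    } else if (bits == 8L) {
      as.integer(readBin(buf, "integer", n = w * h, size = 1L, endian = endian,
                         signed = FALSE))
    } else if (bits == 16L) {
      readBin(buf, "integer", n = w * h, size = 2L, endian = endian,
              signed = FALSE)
    } else if (bits == 32L) {
      readBin(buf, "integer", n = w * h, size = 4L, endian = endian)
    } else stop("unsupported TIFF: ", bits, "-bit samples")
    pages[[length(pages) + 1L]] <- matrix(vals, nrow = h, ncol = w, byrow = TRUE)
    if (is.null(description) && !is.null(tags[["270"]])) {
      description <- tags[["270"]]
    }
    ifd <- rd(ifd + 2L + n * 12L, 1L, 4L)
  }
  list(pages = pages, description = description)
}

#' Write an image scene as a multi-page TIFF
#'
#' Pages are ordered channel-major (all frames of channel 1, then channel
#' 2, ...). Pixel data are stored as 64-bit floats; channel names, pixel
#' size and frame interval are embedded as JSON metadata so that
#' [read_image()] round-trips the scene bit-identically.
#'
#' @param scene an [image_scene()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_image <- function(scene, path) {
  stopifnot(inherits(scene, "ImageScene"))
  d <- dim(scene$channels[[1]])
  n_frames <- if (length(d) == 3L) d[3] else 1L
  pages <- list()
  for (nm in scene$channel_names) {
    ch <- scene$channels[[nm]]
    for (f in seq_len(n_frames)) {
      pages[[length(pages) + 1L]] <- if (n_frames > 1L) ch[, , f] else ch
    }
  }
  meta <- list(memquant = as.character(utils::packageVersion("memquant")),
               channel_names = scene$channel_names,
               pixel_size_um = scene$pixel_size_um,
               frame_interval_s = scene$frame_interval_s,
               n_frames = n_frames)
  desc <- as.character(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA,
                                        null = "null", na = "null"))
  .tiff_write_pages(pages, path, sample_format = 3L, bits = 64L,
                    description = desc)
  invisible(path)
}

#' Read a TIFF / OME-TIFF image into a scene
#'
#' Reads multi-page grayscale TIFFs. Metadata (channel names, pixel size,
#' frame interval) is taken from the embedded JSON written by
#' [write_image()], or from an OME-XML `PhysicalSizeX` attribute, or from
#' the arguments; a missing pixel size is an error, never a silent default.
#'
#' @param path TIFF file.
#' @param channel_names channel labels to assign (and require). With file
#'   metadata present these must be a subset of the stored channels; the
#'   scene is restricted to them. Without metadata their number must equal
#'   the page count.
#' @param pixel_size_um,frame_interval_s metadata fallbacks when the file
#'   carries none.
#' @return an [image_scene()].
#' @export
read_image <- function(path, channel_names = NULL, pixel_size_um = NULL,
                       frame_interval_s = NULL) {
  tf <- .tiff_read_pages(path)
  pages <- tf$pages
  meta <- NULL
  if (!is.null(tf$description)) {
    meta <- tryCatch(jsonlite::fromJSON(tf$description), error = function(e) NULL)
    if (is.null(meta$memquant)) {
      ps <- regmatches(tf$description,
                       regexpr('PhysicalSizeX="[0-9.eE+-]+"', tf$description))
      meta <- if (length(ps)) {
        list(pixel_size_um = as.numeric(gsub('[^0-9.eE+-]', '', sub('PhysicalSizeX=', '', ps))))
      } else NULL
    }
  }
  if (!is.null(meta$memquant)) {
    stored <- meta$channel_names
    n_frames <- meta$n_frames
    if (length(pages) != length(stored) * n_frames) {
      stop("channel-count mismatch: metadata promises ", length(stored),
           " channel(s) x ", n_frames, " frame(s), file has ", length(pages),
           " page(s)")
    }
    want <- if (is.null(channel_names)) stored else channel_names
    missing_ch <- setdiff(want, stored)
    if (length(missing_ch)) {
      stop("requested channel(s) absent from file: ",
           paste(missing_ch, collapse = ", "))
    }
    chans <- list()
    for (nm in want) {
      i <- match(nm, stored)
      pg <- pages[(i - 1L) * n_frames + seq_len(n_frames)]
      chans[[nm]] <- if (n_frames > 1L) {
        array(unlist(pg), dim = c(dim(pg[[1]]), n_frames))
      } else pg[[1]]
    }
    ps <- meta$pixel_size_um
    fi <- if (is.null(meta$frame_interval_s)) NA_real_ else meta$frame_interval_s
    return(image_scene(chans, pixel_size_um = ps, frame_interval_s = fi))
  }
  # no usable metadata beyond (possibly) pixel size
  if (is.null(channel_names)) {
    channel_names <- paste0("Ch", seq_along(pages))
  } else if (length(channel_names) != length(pages)) {
    stop("channel-count mismatch: ", length(channel_names),
         " name(s) for ", length(pages), " page(s)")
  }
  ps <- if (!is.null(meta$pixel_size_um)) meta$pixel_size_um else pixel_size_um
  if (is.null(ps)) {
    stop("pixel size missing: not in file metadata and `pixel_size_um` not given")
  }
  chans <- stats::setNames(pages, channel_names)
  image_scene(chans, pixel_size_um = ps,
              frame_interval_s = if (is.null(frame_interval_s)) NA_real_
                                 else frame_interval_s)
}

#' Write a label mask as a 16-bit TIFF
#'
#' @param mask a [label_mask()] or integer matrix; labels must be <= 65535.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_label_tiff <- function(mask, path) {
  m <- if (inherits(mask, "LabelMask")) mask$labels else mask
  stopifnot(is.matrix(m))
  if (max(m) > 65535L) stop("labels exceed 16-bit range")
  .tiff_write_pages(list(m), path, sample_format = 1L, bits = 16L,
                    description = "memquant label mask")
  invisible(path)
}

#' Read a 16-bit label TIFF
#'
#' @param path TIFF file written by [write_label_tiff()].
#' @return a [label_mask()].
#' @export
read_label_tiff <- function(path) {
  tf <- .tiff_read_pages(path)
  label_mask(tf$pages[[1]])
}
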