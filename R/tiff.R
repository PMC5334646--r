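# Minimal baseline TIFF 6.0 reader/writer for multi-page grayscale stacks.
# Scope: uncompressed, single-sample, 8- or 16-bit unsigned data; both byte
# orders on read, little-endian on write. This is the interchange format of
# the pipeline; anything richer (compression, RGB, tiles) is rejected with a
# clear error. No TIFF package exists in the supported R stack, hence this
# hand-rolled implementation.

.tiff_type_size <- c(`1` = 1, `2` = 1, `3` = 2, `4` = 4, `5` = 8,
                     `6` = 1, `7` = 1, `8` = 2, `9` = 4, `10` = 8,
                     `11` = 4, `12` = 8)

.read_tag_values <- function(con, entry, endian) {
  n_bytes <- .tiff_type_size[as.character(entry$type)] * entry$count
  if (is.na(n_bytes)) return(NULL)
  read_vals <- function() {
    switch(as.character(entry$type),
      `3` = readBin(con, "integer", n = entry$count, size = 2,
                    signed = FALSE, endian = endian),
      `4` = readBin(con, "integer", n = entry$count, size = 4, endian = endian),
      `1` = as.integer(readBin(con, "raw", n = entry$count)),
      NULL)
  }
  if (n_bytes <= 4) {
    cur <- seek(con)
    seek(con, entry$value_offset_pos)
    vals <- read_vals()
    seek(con, cur)
  } else {
    offset <- {
      cur <- seek(con)
      seek(con, entry$value_offset_pos)
      o <- readBin(con, "integer", size = 4, endian = endian)
      seek(con, cur)
      o
    }
    cur <- seek(con)
    seek(con, offset)
    vals <- read_vals()
    seek(con, cur)
  }
  vals
}

.read_tiff <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  byte_order <- readChar(con, 2, useBytes = TRUE)
  endian <- switch(byte_order, II = "little", MM = "big",
                   stop("not a TIFF file: ", path))
  magic <- readBin(con, "integer", size = 2, signed = FALSE, endian = endian)
  if (!identical(magic, 42L)) stop("not a TIFF file: ", path)
  ifd_offset <- readBin(con, "integer", size = 4, endian = endian)
  pages <- list()
  while (!is.na(ifd_offset) && ifd_offset != 0) {
    seek(con, ifd_offset)
    n_entries <- readBin(con, "integer", size = 2, signed = FALSE,
                         endian = endian)
    if (length(n_entries) == 0 || is.na(n_entries)) {
      stop("truncated TIFF file: ", path)
    }
    tags <- list()
    for (i in seq_len(n_entries)) {
      tag <- readBin(con, "integer", size = 2, signed = FALSE, endian = endian)
      type <- readBin(con, "integer", size = 2, signed = FALSE, endian = endian)
      count <- readBin(con, "integer", size = 4, endian = endian)
      value_offset_pos <- seek(con)
      seek(con, value_offset_pos + 4)
      if (length(count) == 0 || is.na(count)) {
        stop("truncated TIFF file: ", path)
      }
      tags[[as.character(tag)]] <-
        list(type = type, count = count, value_offset_pos = value_offset_pos)
    }
    ifd_offset <- readBin(con, "integer", size = 4, endian = endian)
    if (length(ifd_offset) == 0) stop("truncated TIFF file: ", path)
    tagval <- function(id, default = NULL) {
      e <- tags[[as.character(id)]]
      if (is.null(e)) return(default)
      .read_tag_values(con, e, endian)
    }
    width <- tagval(256); height <- tagval(257)
    if (is.null(width) || is.null(height)) {
      stop("TIFF page without dimensions: ", path)
    }
    bits <- tagval(258, 8L)
    compression <- tagval(259, 1L)
    photometric <- tagval(262, 1L)
    spp <- tagval(277, 1L)
    if (!identical(compression, 1L)) {
      stop("unsupported TIFF: compressed data (compression tag ", compression,
           ")")
    }
    if (!identical(spp, 1L) || length(bits) != 1L) {
      stop("unsupported TIFF: multi-channel (RGB?) data; ",
           "expected single-sample grayscale")
    }
    if (!bits %in% c(8L, 16L)) {
      stop("unsupported TIFF: ", bits, "-bit samples (need 8 or 16)")
    }
    if (!photometric %in% c(0L, 1L)) {
      stop("unsupported TIFF: photometric interpretation ", photometric)
    }
    offsets <- tagval(273); counts <- tagval(279)
    if (is.null(offsets) || is.null(counts)) {
      stop("TIFF page without strip layout: ", path)
    }
    n_px <- as.numeric(width) * as.numeric(height)
    vals <- integer(0)
    for (s in seq_along(offsets)) {
      seek(con, offsets[s])
      n_this <- counts[s] %/% (bits %/% 8L)
      v <- readBin(con, "integer", n = n_this, size = bits %/% 8L,
                   signed = FALSE, endian = endian)
      if (length(v) < n_this) stop("truncated TIFF file: ", path)
      vals <- c(vals, v)
    }
    if (length(vals) < n_px) stop("truncated TIFF file: ", path)
    # strip data is row-major; store as (row = y, col = x)
    pages[[length(pages) + 1]] <-
      list(data = matrix(vals[seq_len(n_px)], nrow = height, ncol = width,
                         byrow = TRUE),
           bits = bits)
  }
  if (length(pages) == 0) stop("TIFF file has no pages: ", path)
  bits <- unique(vapply(pages, function(p) p$bits, integer(1)))
  if (length(bits) != 1) stop("mixed bit depths across TIFF pages")
  arr <- array(0, c(nrow(pages[[1]]$data), ncol(pages[[1]]$data),
                    length(pages)))
  for (z in seq_along(pages)) arr[, , z] <- pages[[z]]$data
  list(planes = arr, bit_depth = bits)
}

.uint_to_raw <- function(v, bytes) {
  if (bytes == 1L) return(as.raw(v))
  lo <- as.raw(v %% 256L)
  hi <- as.raw(v %/% 256L)
  as.vector(rbind(lo, hi)) # little-endian pairs
}

.write_tiff <- function(planes, path, bit_depth = 16L) {
  stopifnot(length(dim(planes)) == 3, bit_depth %in% c(8L, 16L))
  maxval <- 2L^bit_depth - 1L
  v <- round(planes)
  if (min(v) < 0 || max(v) > maxval) {
    stop("pixel values out of range for ", bit_depth, "-bit TIFF")
  }
  ny <- dim(planes)[1]; nx <- dim(planes)[2]; nz <- dim(planes)[3]
  bpp <- bit_depth %/% 8L
  strip_bytes <- nx * ny * bpp
  con <- file(path, "wb")
  on.exit(close(con))
  w2 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w4 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  writeChar("II", con, eos = NULL)
  w2(42)
  header_next <- 8 + nz * strip_bytes # first IFD comes after all pixel data
  w4(header_next)
  for (z in seq_len(nz)) {
    row_major <- as.integer(t(v[, , z]))
    writeBin(.uint_to_raw(row_major, bpp), con)
  }
  n_tags <- 9L
  ifd_size <- 2 + n_tags * 12 + 4
  for (z in seq_len(nz)) {
    w2(n_tags)
    entry <- function(tag, type, count, value) {
      w2(tag); w2(type); w4(count)
      if (type == 3) { w2(value); w2(0) } else w4(value)
    }
    entry(256, 4, 1, nx)                      # ImageWidth
    entry(257, 4, 1, ny)                      # ImageLength
    entry(258, 3, 1, bit_depth)               # BitsPerSample
    entry(259, 3, 1, 1)                       # Compression = none
    entry(262, 3, 1, 1)                       # Photometric = BlackIsZero
    entry(273, 4, 1, 8 + (z - 1) * strip_bytes) # StripOffsets
    entry(277, 3, 1, 1)                       # SamplesPerPixel
    entry(278, 4, 1, ny)                      # RowsPerStrip
    entry(279, 4, 1, strip_bytes)             # StripByteCounts
    next_ifd <- if (z < nz) header_next + z * ifd_size else 0
    w4(next_ifd)
  }
  invisible(path)
}

#' Read a 3D image stack from a multi-page grayscale TIFF
#'
#' Reads an uncompressed 8- or 16-bit grayscale TIFF stack. Physical pitches
#' are taken from the arguments, or, when a YAML sidecar `<path>.yaml` with
#' keys `lateral_pitch` / `axial_pitch` exists, from that sidecar.
#'
#' @param path path to the TIFF file.
#' @param lateral_pitch in-plane sampling in micrometres per pixel. The
#'   default corresponds to a 6.5 um camera pixel pitch behind a 20x
#'   objective.
#' @param axial_pitch plane spacing in micrometres.
#'
#' @return A `raw_stack`: list with `planes` (numeric array, dim
#'   `c(ny, nx, nz)`), `lateral_pitch`, `axial_pitch` and `bit_depth`.
#' @export
#' @examples
#' st <- raw_stack(array(c(0, 255), c(4, 4, 2)), lateral_pitch = 0.325,
#'                 axial_pitch = 1.29, bit_depth = 8)
#' tf <- tempfile(fileext = ".tif")
#' write_stack(st, tf)
#' st2 <- read_stack(tf, lateral_pitch = 0.325, axial_pitch = 1.29)
#' identical(st$planes, st2$planes)
read_stack <- function(path, lateral_pitch = 6.5 / 20, axial_pitch = 1.29) {
  if (!file.exists(path)) stop("cannot read stack: no such file: ", path)
  sidecar <- paste0(path, ".yaml")
  if (file.exists(sidecar)) {
    meta <- yaml::read_yaml(sidecar)
    if (!is.null(meta$lateral_pitch)) lateral_pitch <- meta$lateral_pitch
    if (!is.null(meta$axial_pitch)) axial_pitch <- meta$axial_pitch
  }
  img <- .read_tiff(path)
  raw_stack(img$planes, lateral_pitch = lateral_pitch,
            axial_pitch = axial_pitch, bit_depth = img$bit_depth)
}

#' @rdname read_stack
#' @param planes numeric 3D array of non-negative integers, dim
#'   `c(ny, nx, nz)`.
#' @param bit_depth 8 or 16.
#' @export
raw_stack <- function(planes, lateral_pitch, axial_pitch, bit_depth = 16L) {
  stopifnot(length(dim(planes)) == 3, dim(planes)[3] >= 1,
            lateral_pitch > 0, axial_pitch > 0, bit_depth %in% c(8L, 16L))
  structure(list(planes = planes, lateral_pitch = lateral_pitch,
                 axial_pitch = axial_pitch, bit_depth = as.integer(bit_depth)),
            class = "raw_stack")
}

#' @rdname read_stack
#' @param stack a `raw_stack`.
#' @param sidecar write a `<path>.yaml` sidecar recording the pitches?
#' @export
write_stack <- function(stack, path, sidecar = TRUE) {
  stopifnot(inherits(stack, "raw_stack"))
  .write_tiff(stack$planes, path, bit_depth = stack$bit_depth)
  if (sidecar) {
    yaml::write_yaml(list(lateral_pitch = stack$lateral_pitch,
                          axial_pitch = stack$axial_pitch),
                     paste0(path, ".yaml"))
  }
  invisible(path)
}

#' @export
print.raw_stack <- function(x, ...) {
  d <- dim(x$planes)
  cat(sprintf(
    "<raw_stack> %d x %d x %d (y,x,z), %d-bit, %.4g um/px lateral, %.4g um axial\n",
    d[1], d[2], d[3], x$bit_depth, x$lateral_pitch, x$axial_pitch))
  invisible(x)
}

#' Write a label image as a TIFF stack
#'
#' Uses 16-bit pages, or an error when more than 65,535 objects are present
#' (such label maps should be exported split or as CSV; baseline TIFF has no
#' 32-bit integer sample type in this writer).
#'
#' @param labels a [label_image].
#' @param path output path.
#' @export
write_labels <- function(labels, path) {
  stopifnot(inherits(labels, "label_image"))
  if (labels$n_objects > 65535) {
    stop("more than 65,535 objects; export centroid/feature tables instead")
  }
  .write_tiff(labels$labels, path, bit_depth = 16L)
  invisible(path)
}
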