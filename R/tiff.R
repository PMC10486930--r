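# Minimal baseline TIFF codec: uncompressed, 8-bit grayscale, little-endian,
# multi-page. No TIFF library ships with the supported R stack, and the only
# TIFFs this package touches are its own synthetic stacks, so the codec stays
# deliberately small: enough of TIFF 6.0 baseline for lossless round-trips of
# one-sample-per-pixel 8-bit pages.

TIFF_TAGS <- c(width = 256L, length = 257L, bps = 258L, compression = 259L,
               photometric = 262L, strip_offsets = 273L, spp = 277L,
               rows_per_strip = 278L, strip_bytes = 279L)

#' Write a 3D 8-bit volume as a multi-page TIFF
#'
#' One page per z-slice, uncompressed 8-bit grayscale, little-endian.
#' Array layout is `[x, y, z]`; a page row corresponds to fixed `y`.
#'
#' @param vol integer/numeric array (2D or 3D) with values in 0..255.
#' @param path output file.
#' @return `path`, invisibly.
#' @seealso [read_tiff_stack()]
#' @export
write_tiff_stack <- function(vol, path) {
  vol <- as_vol(vol)
  if (any(vol < 0 | vol > 255 | vol != floor(vol)))
    stop_gq("volume must hold integers in 0..255")
  d <- dim(vol)
  w <- d[1]; h <- d[2]; nz <- d[3]
  con <- file(path, "wb")
  on.exit(close(con))
  wr2 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  wr4 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  writeBin(charToRaw("II"), con); wr2(42L)
  # layout per page: [pixel data][IFD]; header points at first IFD
  page_bytes <- w * h
  ifd_entries <- 9L
  ifd_bytes <- 2L + ifd_entries * 12L + 4L
  first_ifd <- 8L + page_bytes
  wr4(first_ifd)
  entry <- function(tag, type, count, value) { wr2(tag); wr2(type); wr4(count); wr4(value) }
  for (z in seq_len(nz)) {
    page_start <- 8L + (z - 1L) * (page_bytes + ifd_bytes)
    # pixel data, row-major: x varies fastest within a row of constant y
    writeBin(as.raw(as.integer(vol[, , z])), con)
    wr2(ifd_entries)
    entry(TIFF_TAGS[["width"]], 3L, 1L, w)
    entry(TIFF_TAGS[["length"]], 3L, 1L, h)
    entry(TIFF_TAGS[["bps"]], 3L, 1L, 8L)
    entry(TIFF_TAGS[["compression"]], 3L, 1L, 1L)
    entry(TIFF_TAGS[["photometric"]], 3L, 1L, 1L)  # BlackIsZero
    entry(TIFF_TAGS[["strip_offsets"]], 4L, 1L, page_start)
    entry(TIFF_TAGS[["spp"]], 3L, 1L, 1L)
    entry(TIFF_TAGS[["rows_per_strip"]], 3L, 1L, h)
    entry(TIFF_TAGS[["strip_bytes"]], 4L, 1L, page_bytes)
    next_ifd <- if (z < nz) page_start + 2L * page_bytes + ifd_bytes else 0L
    wr4(next_ifd)
  }
  invisible(path)
}

#' Read a multi-page 8-bit grayscale TIFF into a 3D array
#'
#' Supports the baseline subset written by [write_tiff_stack()]: uncompressed
#' 8-bit single-sample pages (any number of strips), either byte order.
#'
#' @param path TIFF file.
#' @return integer array `[x, y, z]`.
#' @export
read_tiff_stack <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 8L) stop_gq("not a TIFF file: %s", path)
  order_tag <- rawToChar(raw[1:2])
  endian <- switch(order_tag, II = "little", MM = "big",
                   stop_gq("not a TIFF file: %s", path))
  u16 <- function(off) readBin(raw[(off + 1):(off + 2)], "integer", size = 2,
                               endian = endian, signed = FALSE)
  u32 <- function(off) readBin(raw[(off + 1):(off + 4)], "integer", size = 4, endian = endian)
  if (u16(2) != 42L) stop_gq("not a TIFF file: %s", path)
  ifd <- u32(4)
  pages <- list()
  while (ifd != 0L) {
    n <- u16(ifd)
    tags <- list()
    for (i in seq_len(n)) {
      e <- ifd + 2L + (i - 1L) * 12L
      tag <- u16(e); type <- u16(e + 2); count <- u32(e + 4)
      val <- if (type == 3L && count == 1L) u16(e + 8) else u32(e + 8)
      if (count > 1L) {           # value is an offset to an array
        off <- u32(e + 8)
        rd <- if (type == 3L) function(k) u16(off + (k - 1L) * 2L) else function(k) u32(off + (k - 1L) * 4L)
        val <- vapply(seq_len(count), rd, integer(1))
      }
      tags[[as.character(tag)]] <- val
    }
    g <- function(id, default = NULL) tags[[as.character(id)]] %||% default
    if ((g(259L, 1L))[1] != 1L) stop_gq("only uncompressed TIFF supported")
    if ((g(258L, 8L))[1] != 8L || (g(277L, 1L))[1] != 1L)
      stop_gq("only 8-bit single-sample TIFF supported")
    w <- g(256L); h <- g(257L)
    offs <- g(273L); nbytes <- g(279L, w * h)
    bytes <- unlist(lapply(seq_along(offs), function(k)
      raw[(offs[k] + 1):(offs[k] + nbytes[k])]))
    page <- matrix(as.integer(bytes), nrow = w, ncol = h)  # x fastest
    pages[[length(pages) + 1L]] <- page
    ifd <- u32(ifd + 2L + n * 12L)
  }
  d1 <- dim(pages[[1]])
  array(unlist(pages), dim = c(d1, length(pages)))
}
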