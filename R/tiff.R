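# Minimal multi-page 16-bit grayscale TIFF I/O (little-endian, uncompressed,
# one strip per page). No TIFF library exists in the supported R stack, so
# this implements exactly the baseline subset the pipeline needs: Z (or T)
# pages of a single-channel volume, ImageJ-compatible page order.

TIFF_TAGS <- c(ImageWidth = 256L, ImageLength = 257L, BitsPerSample = 258L,
               Compression = 259L, Photometric = 262L, StripOffsets = 273L,
               RowsPerStrip = 278L, StripByteCounts = 279L,
               SampleFormat = 339L)

#' Write a 3D array as a multi-page 16-bit grayscale TIFF
#'
#' Pages are the third array dimension (Z or T); within a page, rows are the
#' second dimension (Y) and columns the first (X). Values are clamped to
#' `[0, 65535]` and rounded.
#'
#' @param a 3D numeric array `[x, y, z]` (a 2D matrix is treated as one
#'   page).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tiff16 <- function(a, path) {
  if (length(dim(a)) == 2) dim(a) <- c(dim(a), 1)
  stopifnot(length(dim(a)) == 3)
  d <- dim(a)
  vals <- pmin(pmax(round(a), 0), 65535)  # order keeps dim attributes
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size,
                                   endian = "little")
  n_entries <- length(TIFF_TAGS)
  ifd_size <- 2 + n_entries * 12 + 4
  page_bytes <- d[1] * d[2] * 2
  # header: byte order, magic, offset of the first IFD (data precedes it)
  writeBin(charToRaw("II"), con)
  wi(42, 2)
  wi(8 + page_bytes, 4)
  # layout: header (8) | per page: [pixel data][IFD]
  offset <- 8
  for (p in seq_len(d[3])) {
    data_off <- offset
    ifd_off <- data_off + page_bytes
    # pixel data, row-major (y rows, x fastest)
    page <- as.vector(vals[, , p])
    writeBin(as.integer(page), con, size = 2, endian = "little")
    # IFD
    wi(n_entries, 2)
    entry <- function(tag, type, value) {
      wi(tag, 2); wi(type, 2); wi(1, 4)
      if (type == 3) { wi(value, 2); wi(0, 2) } else wi(value, 4)
    }
    entry(TIFF_TAGS[["ImageWidth"]], 4L, d[1])
    entry(TIFF_TAGS[["ImageLength"]], 4L, d[2])
    entry(TIFF_TAGS[["BitsPerSample"]], 3L, 16)
    entry(TIFF_TAGS[["Compression"]], 3L, 1)
    entry(TIFF_TAGS[["Photometric"]], 3L, 1)
    entry(TIFF_TAGS[["StripOffsets"]], 4L, data_off)
    entry(TIFF_TAGS[["RowsPerStrip"]], 4L, d[2])
    entry(TIFF_TAGS[["StripByteCounts"]], 4L, page_bytes)
    entry(TIFF_TAGS[["SampleFormat"]], 3L, 1)
    next_ifd <- if (p < d[3]) ifd_off + ifd_size + page_bytes else 0
    wi(next_ifd, 4)
    offset <- ifd_off + ifd_size
  }
  invisible(path)
}

#' Read a multi-page 16-bit grayscale TIFF into a 3D array
#'
#' Supports the baseline uncompressed subset written by [write_tiff16()]
#' (and by common writers using little-endian, single-sample, 16-bit,
#' strip-based layout).
#'
#' @param path TIFF file path.
#' @return 3D integer array `[x, y, z]`.
#' @export
read_tiff16 <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  u16 <- function(off) sum(as.integer(raw[off + 1:2]) * c(1, 256))
  u32 <- function(off) sum(as.numeric(raw[off + 1:4]) * 256^(0:3))
  if (rawToChar(raw[1:2]) != "II" || u16(2) != 42) {
    stop("not a little-endian TIFF")
  }
  ifd <- u32(4)
  pages <- list()
  while (ifd != 0) {
    n <- u16(ifd)
    tags <- list()
    for (e in seq_len(n)) {
      base <- ifd + 2 + (e - 1) * 12
      tag <- u16(base)
      type <- u16(base + 2)
      count <- u32(base + 4)
      val <- if (type == 3 && count == 1) u16(base + 8) else u32(base + 8)
      tags[[as.character(tag)]] <- list(type = type, count = count,
                                        value = val, off = base + 8)
    }
    need <- function(tag) {
      t <- tags[[as.character(tag)]]
      if (is.null(t)) stop("missing TIFF tag ", tag)
      t
    }
    # all values of a SHORT/LONG tag, inline when they fit in 4 bytes
    tag_values <- function(t) {
      size <- if (t$type == 3) 2 else 4
      rd <- if (t$type == 3) u16 else u32
      base <- if (t$count * size <= 4) t$off else t$value
      vapply(seq_len(t$count) - 1, function(i) rd(base + size * i), 1)
    }
    w <- need(256)$value; h <- need(257)$value
    if (any(tag_values(need(258)) != 16)) stop("only 16-bit TIFF supported")
    if (need(259)$value != 1) stop("only uncompressed TIFF supported")
    spp <- tags[["277"]]
    if (!is.null(spp) && spp$value != 1) {
      stop("only single-sample (grayscale) TIFF supported")
    }
    offs <- tag_values(need(273))
    cnts <- tag_values(need(279))
    pix <- integer(0)
    for (s in seq_along(offs)) {
      nb <- cnts[s]
      bytes <- raw[offs[s] + seq_len(nb)]
      pix <- c(pix, readBin(bytes, "integer", n = nb / 2, size = 2,
                            signed = FALSE, endian = "little"))
    }
    pages[[length(pages) + 1]] <- matrix(pix, nrow = w)
    ifd <- u32(ifd + 2 + n * 12)
  }
  d1 <- nrow(pages[[1]]); d2 <- ncol(pages[[1]])
  array(unlist(pages), dim = c(d1, d2, length(pages)))
}

#' Write a voxel render to one TIFF per channel
#'
#' Writes each channel of a [render_voxels()] output as a multi-page TIFF
#' whose pages run over Z within frame, frames concatenated (TZYX order when
#' read plane-by-plane).
#'
#' @param voxels output of [render_voxels()].
#' @param dir output directory.
#' @param prefix file-name prefix.
#' @return named character vector of written paths.
#' @export
write_voxels_tiff <- function(voxels, dir, prefix = "stack") {
  channels <- names(voxels[[1]])
  out <- character()
  for (ch in channels) {
    vols <- lapply(voxels, `[[`, ch)
    big <- array(unlist(vols),
                 dim = c(dim(vols[[1]])[1:2],
                         dim(vols[[1]])[3] * length(vols)))
    path <- file.path(dir, paste0(prefix, "_", ch, ".tif"))
    write_tiff16(big, path)
    out[ch] <- path
  }
  out
}
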