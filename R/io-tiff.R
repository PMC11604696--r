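# Minimal baseline-TIFF I/O: uncompressed 16-bit greyscale, little-endian,
# one page per channel, one strip per page. No imaging package ships a TIFF
# codec in this environment, so the few tags we need are written by hand.
# Channel names and pixel calibration travel in a JSON sidecar
# (<image>.json) because baseline TIFF has no standard slot for them.

TIFF_TAGS <- c(width = 256L, length = 257L, bits = 258L, compression = 259L,
               photometric = 262L, strip_offsets = 273L, samples = 277L,
               rows_per_strip = 278L, strip_bytes = 279L, sample_format = 339L)

#' Write a multi-channel image as a multi-page TIFF
#'
#' One greyscale 16-bit page per channel, in the order of
#' `image$channel_names` (nuclear channel first by the package's generator
#' convention). A sidecar `<path>.json` records channel names, pixel size
#' and bit depth.
#'
#' @param image an `islet_image`.
#' @param path output file path (`.tif`).
#' @return `path`, invisibly.
#' @export
write_image_tiff <- function(image, path) {
  stopifnot(inherits(image, "islet_image"))
  full <- 2^image$bit_depth - 1
  for (p in image$planes)
    if (any(p < 0) || any(p > full))
      stop("intensities exceed the declared ", image$bit_depth, "-bit dynamic range")
  con <- file(path, "wb")
  on.exit(close(con))
  w16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  writeChar("II", con, nchars = 2, eos = NULL)
  w16(42L)
  n <- length(image$planes)
  nr <- nrow(image$planes[[1]]); nc <- ncol(image$planes[[1]])
  nbytes <- nr * nc * 2
  # layout: header(8) | page data blocks | IFDs (10 entries each)
  data_off <- 8 + (seq_len(n) - 1) * nbytes
  ifd_size <- 2 + 10 * 12 + 4
  ifd_off <- 8 + n * nbytes + (seq_len(n) - 1) * ifd_size
  w32(ifd_off[1])
  for (p in image$planes) {
    v <- as.integer(round(t(p)))            # TIFF scanlines are row-major
    v[v > 32767L] <- v[v > 32767L] - 65536L # two's complement for writeBin
    writeBin(v, con, size = 2, endian = "little")
  }
  entry <- function(tag, type, value) { # type 3 = SHORT, 4 = LONG
    w16(tag); w16(type); w32(1L)
    if (type == 3L) { w16(value); w16(0L) } else w32(value)
  }
  for (i in seq_len(n)) {
    w16(10L)
    entry(TIFF_TAGS[["width"]], 4L, nc)
    entry(TIFF_TAGS[["length"]], 4L, nr)
    entry(TIFF_TAGS[["bits"]], 3L, 16L)
    entry(TIFF_TAGS[["compression"]], 3L, 1L)
    entry(TIFF_TAGS[["photometric"]], 3L, 1L)
    entry(TIFF_TAGS[["strip_offsets"]], 4L, data_off[i])
    entry(TIFF_TAGS[["samples"]], 3L, 1L)
    entry(TIFF_TAGS[["rows_per_strip"]], 4L, nr)
    entry(TIFF_TAGS[["strip_bytes"]], 4L, nbytes)
    entry(TIFF_TAGS[["sample_format"]], 3L, 1L)
    w32(if (i < n) ifd_off[i + 1] else 0L)
  }
  meta <- list(channel_names = image$channel_names,
               pixel_size_um = image$pixel_size_um,
               bit_depth = image$bit_depth)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a multi-page TIFF written by [write_image_tiff()]
#'
#' Supports uncompressed 16-bit greyscale little-endian TIFF with one strip
#' per page. Calibration and channel names are taken from the JSON sidecar;
#' if absent, `pixel_size_um` must be supplied.
#'
#' @param path TIFF file path.
#' @param pixel_size_um fallback calibration when no sidecar exists.
#' @return an `islet_image`.
#' @export
read_image_tiff <- function(path, pixel_size_um = NULL) {
  raw <- readBin(path, "raw", file.info(path)$size)
  u16 <- function(off) sum(as.integer(raw[off + 1:2]) * c(1, 256))
  u32 <- function(off) sum(as.numeric(as.integer(raw[off + 1:4])) * c(1, 256, 65536, 16777216))
  if (rawToChar(raw[1:2]) != "II" || u16(2) != 42L)
    stop("not a little-endian TIFF file: ", path)
  planes <- list()
  ifd <- u32(4)
  while (ifd != 0) {
    nent <- u16(ifd)
    tags <- list()
    for (k in seq_len(nent)) {
      e <- ifd + 2 + (k - 1) * 12
      tag <- u16(e); type <- u16(e + 2)
      val <- if (type == 3L) u16(e + 8) else u32(e + 8)
      tags[[as.character(tag)]] <- val
    }
    need <- function(t) {
      v <- tags[[as.character(TIFF_TAGS[[t]])]]
      if (is.null(v)) stop("TIFF page missing required tag: ", t)
      v
    }
    if (!is.null(tags[["259"]]) && tags[["259"]] != 1L)
      stop("compressed TIFF not supported")
    if (!is.null(tags[["258"]]) && tags[["258"]] != 16L)
      stop("only 16-bit TIFF supported")
    nc <- need("width"); nr <- need("length"); off <- need("strip_offsets")
    v <- readBin(raw[(off + 1):(off + nr * nc * 2)], "integer",
                 n = nr * nc, size = 2, signed = FALSE, endian = "little")
    planes[[length(planes) + 1]] <- t(matrix(v, nrow = nc, ncol = nr))
    ifd <- u32(ifd + 2 + nent * 12)
  }
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    multichannel_image(planes, meta$channel_names, meta$pixel_size_um,
                       meta$bit_depth)
  } else {
    if (is.null(pixel_size_um))
      stop("no sidecar metadata found for ", path,
           "; supply 'pixel_size_um' explicitly")
    multichannel_image(planes, paste0("ch", seq_along(planes)), pixel_size_um)
  }
}
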