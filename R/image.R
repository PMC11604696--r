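#' Multi-channel calibrated image
#'
#' The raw substrate of all measurement: a stack of identically shaped 2D
#' intensity planes, one per channel, with pixel-size calibration. Intensities
#' are stored as doubles but are expected to lie within `[0, 2^bit_depth - 1]`.
#'
#' @param planes named list of numeric matrices, identical dimensions.
#' @param channel_names character vector; defaults to `names(planes)`.
#' @param pixel_size_um physical pixel edge length in micrometres (> 0).
#' @param bit_depth declared bit depth (default 16).
#' @return an object of class `islet_image`.
#' @export
multichannel_image <- function(planes, channel_names = names(planes),
                               pixel_size_um, bit_depth = 16L) {
  if (!is.list(planes) || length(planes) == 0)
    stop("'planes' must be a non-empty list of matrices")
  if (is.null(channel_names) || length(channel_names) != length(planes))
    stop("one channel name per plane is required")
  dims <- lapply(planes, dim)
  if (any(vapply(planes, function(p) !is.matrix(p) || !is.numeric(p), logical(1))))
    stop("all planes must be numeric matrices")
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1)
    stop("all planes must have identical dimensions")
  if (anyDuplicated(channel_names)) stop("channel names must be unique")
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1 || pixel_size_um <= 0)
    stop("'pixel_size_um' must be a single positive number")
  if (any(vapply(planes, function(p) any(p < 0), logical(1))))
    stop("negative intensities are not allowed")
  names(planes) <- channel_names
  structure(list(planes = planes, channel_names = channel_names,
                 pixel_size_um = pixel_size_um, bit_depth = as.integer(bit_depth)),
            class = "islet_image")
}

#' @export
print.islet_image <- function(x, ...) {
  d <- dim(x$planes[[1]])
  cat(sprintf("islet_image: %d x %d px, %d channel(s) [%s], %.3g um/px, %d-bit\n",
              d[1], d[2], length(x$planes),
              paste(x$channel_names, collapse = ", "),
              x$pixel_size_um, x$bit_depth))
  invisible(x)
}

#' Extract one channel plane
#'
#' @param image an `islet_image`.
#' @param channel channel name or index.
#' @return the numeric intensity matrix of that channel.
#' @export
get_plane <- function(image, channel) {
  stopifnot(inherits(image, "islet_image"))
  if (is.character(channel) && !channel %in% image$channel_names)
    stop("unknown channel '", channel, "'; available: ",
         paste(image$channel_names, collapse = ", "))
  image$planes[[channel]]
}

# Area of a pixel-count in um^2 under the image calibration.
px_to_um2 <- function(n_px, pixel_size_um) n_px * pixel_size_um^2
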