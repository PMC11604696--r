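# Whole-islet quantification arm: alignment, illumination correction, Otsu
# islet detection on the summed endocrine marker channels, background
# subtraction outside the islet masks, per-islet occupied-area fractions,
# intensities and Manders co-localisation.

#' Align channels to a reference by integer translation
#'
#' Each non-reference plane is shifted by the integer translation that
#' maximises its circular cross-correlation (computed by FFT) with the
#' reference channel. Estimated shifts larger than `max_shift_px` are
#' treated as spurious: a warning is raised and the plane is left unshifted.
#'
#' @param image an `islet_image`.
#' @param reference_channel channel name used as registration target.
#' @param max_shift_px maximum credible shift (default 10 px).
#' @param channels channels to align (default: all); planes outside this
#'   set are passed through untouched.
#' @return the realigned `islet_image`, with attribute `shifts` (matrix of
#'   applied (row, col) shifts per channel).
#' @export
align_channels <- function(image, reference_channel = image$channel_names[1],
                           max_shift_px = 10L,
                           channels = image$channel_names) {
  stopifnot(inherits(image, "islet_image"))
  # register on low-pass versions: the punctate granule texture differs
  # between channels (and can even anti-correlate at lag 0); the shared
  # cell-scale structure is what carries the registration signal
  lp <- function(p) gaussian_blur(p, 1.5)
  ref <- lp(get_plane(image, reference_channel))
  Fr <- fft(ref - mean(ref))
  shifts <- matrix(0L, length(image$planes), 2,
                   dimnames = list(image$channel_names, c("row", "col")))
  for (ch in intersect(image$channel_names, channels)) {
    if (ch == reference_channel) next
    orig <- image$planes[[ch]]
    p <- lp(orig)
    cc <- Re(fft(Fr * Conj(fft(p - mean(p))), inverse = TRUE))
    peak <- which.max(cc)
    dr <- (peak - 1L) %% nrow(cc)
    dc <- (peak - 1L) %/% nrow(cc)
    if (dr > nrow(cc) / 2) dr <- dr - nrow(cc)
    if (dc > ncol(cc) / 2) dc <- dc - ncol(cc)
    if (abs(dr) > max_shift_px || abs(dc) > max_shift_px) {
      warning("channel '", ch, "': estimated shift (", dr, ", ", dc,
              ") exceeds max_shift_px = ", max_shift_px,
              "; leaving channel unshifted")
      next
    }
    if (dr != 0 || dc != 0) {
      image$planes[[ch]] <- roll_matrix(orig, dr, dc)
      shifts[ch, ] <- c(dr, dc)
    }
  }
  attr(image, "shifts") <- shifts
  image
}

#' Flat-field illumination correction
#'
#' Divides the plane by a heavily Gaussian-smoothed version of itself (the
#' estimated illumination field) and rescales so the global mean intensity
#' is preserved. `smoothing_scale_um` must be much larger than one cell
#' diameter, otherwise real objects are flattened too.
#'
#' @param plane numeric intensity matrix.
#' @param smoothing_scale_um Gaussian sigma of the field estimate, in um.
#' @param pixel_size_um calibration.
#' @return corrected plane with the same global mean.
#' @export
correct_illumination <- function(plane, smoothing_scale_um = 100,
                                 pixel_size_um = 0.5) {
  stopifnot(is.matrix(plane), smoothing_scale_um > 0)
  sigma <- smoothing_scale_um / pixel_size_um
  field <- gaussian_blur(plane, sigma)
  eps <- 1e-6 * max(mean(plane), 1e-12)
  if (any(field <= eps)) {
    warning("smoothed illumination field contains near-zero values; flooring")
    field[field <= eps] <- eps
  }
  out <- plane / field
  out * mean(plane) / mean(out)
}

#' Detect islets by Otsu thresholding of summed marker channels
#'
#' The endocrine marker planes are summed, thresholded at the Otsu level,
#' cleaned by morphological closing (disk of one nominal cell radius) and
#' hole filling, and split into connected components; each component is
#' then restricted to its stained-tissue pixels (above the robust
#' background floor), so dim marker-negative cells belong to the islet
#' while unstained interstitial space does not. Components smaller than
#' `min_area_um2` (default `min_cells` x a nominal per-cell tissue
#' footprint `cell_footprint_um2`) are discarded, enforcing the >= 10
#' cells-per-cluster rule.
#'
#' @param image an `islet_image` (aligned, illumination-corrected).
#' @param marker_channels channels whose sum defines endocrine tissue.
#' @param min_cells minimum cells per islet (default 10).
#' @param min_area_um2 explicit area floor; overrides the footprint rule.
#' @param cell_footprint_um2 nominal per-cell tissue footprint (default 120).
#' @param closing_radius_um closing disk radius (default 5 um, one cell
#'   radius).
#' @param min_bright_frac minimum fraction of marker-positive pixels a
#'   component must contain to qualify as an islet (default 0.08;
#'   dim-cell-rich islets of long-standing disease sit near 0.15, exocrine
#'   sheets below 0.03).
#' @return list of islet objects, each `list(islet_id, pixels, dims,
#'   area_um2)`; empty list when nothing survives.
#' @export
detect_islets <- function(image, marker_channels, min_cells = 10L,
                          min_area_um2 = NULL, cell_footprint_um2 = 120,
                          closing_radius_um = 5, min_bright_frac = 0.08) {
  stopifnot(inherits(image, "islet_image"),
            all(marker_channels %in% image$channel_names))
  if (is.null(min_area_um2)) min_area_um2 <- min_cells * cell_footprint_um2
  s <- Reduce(`+`, image$planes[marker_channels])
  if (max(s) <= min(s)) return(list())
  # Otsu on the log-transformed sum. Depending on how much dim
  # (marker-negative) tissue the field carries, the first cut lands either
  # between background and tissue or between tissue and marker-positive
  # cells; a second cut above it always isolates the bright endocrine
  # signal, and components are then required to be predominantly bright
  # (the endocrine-purity criterion standing in for a trained pixel
  # classifier) so that sheets of dim exocrine tissue never pass as islets.
  thr <- expm1(as.numeric(otsu_threshold(log1p(s))))
  up <- s[s >= thr]
  thr_hi <- if (length(up) > 2 && max(up) > min(up))
    expm1(as.numeric(otsu_threshold(log1p(up)))) else thr
  mask <- matrix(as.integer(s >= thr), nrow(s))
  r_px <- closing_radius_um / image$pixel_size_um
  mask <- .erode_disk(.dilate_disk(mask, r_px), r_px)
  mask <- .fill_holes(mask)
  lab <- .cc_label(mask)
  if (max(lab) == 0L) return(list())
  bright <- rowsum(as.numeric(s[lab > 0L] >= thr_hi), lab[lab > 0L])
  tot <- tabulate(lab[lab > 0L], nbins = max(lab))
  purity <- as.numeric(bright[, 1]) / tot[sort(unique(lab[lab > 0L]))]
  impure <- sort(unique(lab[lab > 0L]))[purity < min_bright_frac]
  lab[lab %in% impure] <- 0L
  # an islet object is the stained tissue inside its closed component:
  # dim (marker-negative) cells stay in, interstitial gaps and background
  # bridged by the closing drop out. The tissue floor is the robust
  # background level + 6 MAD estimated outside all components.
  tissue <- tissue_support(s, lab == 0L)
  lab[!tissue] <- 0L
  areas_px <- label_areas(lab)
  keep <- which(px_to_um2(areas_px, image$pixel_size_um) >= min_area_um2)
  out <- vector("list", length(keep))
  for (i in seq_along(keep)) {
    out[[i]] <- list(islet_id = i, pixels = which(lab == keep[i]),
                     dims = dim(lab),
                     area_um2 = px_to_um2(areas_px[keep[i]],
                                          image$pixel_size_um))
  }
  out
}

# Union mask (logical matrix) of a list of islet objects
islet_union_mask <- function(islets, dims) {
  m <- matrix(FALSE, dims[1], dims[2])
  for (isl in islets) m[isl$pixels] <- TRUE
  m
}

#' Subtract the non-islet background from every channel
#'
#' Per channel, the median intensity outside all islet masks is subtracted
#' and negatives are clipped to zero — the islet masks serve as the
#' background definition.
#'
#' @param image an `islet_image`.
#' @param islet_masks list of islet objects from [detect_islets()].
#' @return background-subtracted `islet_image`, with attribute
#'   `background` (named per-channel subtracted medians).
#' @export
subtract_background <- function(image, islet_masks) {
  stopifnot(inherits(image, "islet_image"))
  dims <- dim(image$planes[[1]])
  outside <- !islet_union_mask(islet_masks, dims)
  if (!any(outside))
    stop("islet masks cover the entire image; background is undefined")
  bg <- vapply(image$planes, function(p) median(p[outside]), numeric(1))
  for (ch in seq_along(image$planes)) {
    p <- image$planes[[ch]] - bg[ch]
    p[p < 0] <- 0
    image$planes[[ch]] <- p
  }
  attr(image, "background") <- bg
  image
}

#' Manders co-localisation coefficients
#'
#' `M1` is the fraction of channel-A intensity (over A-positive pixels) that
#' falls on pixels also positive for B; `M2` symmetrically for B. Both lie
#' in `[0, 1]`. Returns `NA` with a warning for a channel with no positive
#' pixels.
#'
#' @param intensities_a,intensities_b equal-length intensity vectors
#'   (typically a plane restricted to a region of interest).
#' @param threshold_a,threshold_b positivity thresholds; a pixel is positive
#'   when intensity >= threshold.
#' @return named numeric `c(M1, M2)`.
#' @export
manders_coefficients <- function(intensities_a, intensities_b,
                                 threshold_a, threshold_b) {
  stopifnot(length(intensities_a) == length(intensities_b))
  pa <- intensities_a >= threshold_a
  pb <- intensities_b >= threshold_b
  den_a <- sum(intensities_a[pa])
  den_b <- sum(intensities_b[pb])
  m1 <- if (den_a > 0) sum(intensities_a[pa & pb]) / den_a else {
    warning("no A-positive pixels; M1 undefined"); NA_real_
  }
  m2 <- if (den_b > 0) sum(intensities_b[pa & pb]) / den_b else {
    warning("no B-positive pixels; M2 undefined"); NA_real_
  }
  c(M1 = m1, M2 = m2)
}

#' Measure one islet: areas, intensities, co-localisation
#'
#' Occupied-area fraction per channel is the fraction of islet-mask pixels
#' at or above the channel's positivity threshold; mean and median
#' intensities are computed over the mask; Manders pairs for the requested
#' channel pairs. Thresholds default to per-channel Otsu over the
#' within-mask pixels ("optimised thresholds"), overridable.
#'
#' @param islet an islet object from [detect_islets()].
#' @param image background-subtracted `islet_image`.
#' @param channels marker channels to measure (default: all but the first,
#'   assumed nuclear).
#' @param thresholds optional named per-channel thresholds.
#' @param manders_pairs list of 2-vectors of channel names; default: all
#'   marker pairs.
#' @return one-row `data.table` of measurements.
#' @export
measure_islet <- function(islet, image, channels = image$channel_names[-1],
                          thresholds = NULL, manders_pairs = NULL) {
  stopifnot(inherits(image, "islet_image"))
  if (length(islet$pixels) == 0) stop("empty islet mask")
  if (is.null(manders_pairs))
    manders_pairs <- utils::combn(channels, 2, simplify = FALSE)
  # area thresholds: Otsu on log intensities (log compresses the punctate
  # granule tail, so the cut separates negative from positive cytoplasm
  # rather than base from granules)
  thr <- numeric(0)
  for (ch in channels) {
    v <- image$planes[[ch]][islet$pixels]
    thr[ch] <- if (!is.null(thresholds) && ch %in% names(thresholds))
      thresholds[[ch]]
    else if (max(v) > min(v)) expm1(as.numeric(otsu_threshold(log1p(v))))
    else Inf
  }
  row <- data.table::data.table(islet_id = islet$islet_id,
                                area_um2 = islet$area_um2)
  full <- 2^image$bit_depth - 1
  for (ch in channels) {
    v <- image$planes[[ch]][islet$pixels]
    row[[paste0("frac_", ch)]] <- mean(v >= thr[ch])
    row[[paste0("mean_", ch)]] <- mean(v)
    row[[paste0("median_", ch)]] <- median(v)
    row[[paste0("mean_rfu_", ch)]] <- mean(v) / full
    row[[paste0("thr_", ch)]] <- unname(thr[ch])
  }
  # co-localisation thresholds: second-stage Otsu over the above-threshold
  # pixels, isolating the punctate (granule-level) signal from the diffuse
  # cytoplasmic base; falls back to the area threshold when degenerate
  thr2 <- thr
  for (ch in channels) {
    v <- image$planes[[ch]][islet$pixels]
    v2 <- v[v >= thr[ch]]
    if (length(v2) >= 2 && max(v2) > min(v2))
      thr2[ch] <- as.numeric(otsu_threshold(v2))
  }
  for (pr in manders_pairs) {
    a <- image$planes[[pr[1]]][islet$pixels]
    b <- image$planes[[pr[2]]][islet$pixels]
    mm <- suppressWarnings(manders_coefficients(a, b, thr2[pr[1]], thr2[pr[2]]))
    row[[paste0("m1_", pr[1], "_", pr[2])]] <- mm[["M1"]]
    row[[paste0("m2_", pr[1], "_", pr[2])]] <- mm[["M2"]]
    row[[paste0("coloc_thr_", pr[1])]] <- unname(thr2[pr[1]])
    row[[paste0("coloc_thr_", pr[2])]] <- unname(thr2[pr[2]])
  }
  row
}

#' Whole-islet analysis of one image
#'
#' Full islet-level arm: channel alignment, illumination correction, islet
#' detection, background subtraction and per-islet measurement.
#'
#' @param image an `islet_image` (nuclear channel first).
#' @param marker_channels marker channels (default: all but first).
#' @param min_cells,closing_radius_um,thresholds see [detect_islets()] and
#'   [measure_islet()].
#' @param align,illumination_correct stage toggles.
#' @param smoothing_scale_um illumination-field scale.
#' @return `data.table` of per-islet measurements (zero rows if no islets),
#'   with the processed image and masks in attributes `image` and `islets`.
#' @export
analyze_islets <- function(image, marker_channels = image$channel_names[-1],
                           min_cells = 10L, closing_radius_um = 5,
                           thresholds = NULL, align = TRUE,
                           illumination_correct = FALSE,
                           smoothing_scale_um = 100) {
  if (align) # markers register against the first marker; the nuclear plane
    # correlates poorly with hormone channels (nuclei are holes in the
    # cytoplasmic signal) and is left untouched
    image <- align_channels(image, reference_channel = marker_channels[1],
                            channels = marker_channels)
  if (illumination_correct)
    for (ch in image$channel_names)
      image$planes[[ch]] <- correct_illumination(
        image$planes[[ch]], smoothing_scale_um, image$pixel_size_um)
  islets <- detect_islets(image, marker_channels, min_cells = min_cells,
                          closing_radius_um = closing_radius_um)
  if (length(islets) == 0) {
    res <- data.table::data.table(islet_id = integer(0), area_um2 = numeric(0))
    attr(res, "image") <- image
    attr(res, "islets") <- islets
    return(res)
  }
  image <- subtract_background(image, islets)
  res <- data.table::rbindlist(
    lapply(islets, measure_islet, image = image, channels = marker_channels,
           thresholds = thresholds), fill = TRUE)
  attr(res, "image") <- image
  attr(res, "islets") <- islets
  res
}
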