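# Single-cell quantification arm: nucleus detection (LoG blobs + seeded
# watershed as a classical stand-in for a trained star-convex detector),
# Voronoi-bounded cytoplasm expansion, per-cell measurement, Otsu-derived
# positivity thresholds, combinatorial phenotyping and per-cell
# co-localisation.

#' Detect nuclei on the nuclear channel
#'
#' Blob detection at the expected nuclear scale: Gaussian smoothing,
#' local-maximum seeds (minimum separation ~0.6 nuclear diameters) within
#' the Otsu foreground of the nuclear plane, then a seeded watershed on the
#' smoothed plane to split touching nuclei. Nuclei overlapping an islet
#' mask are flagged endocrine candidates.
#'
#' @param nuclear_plane intensity matrix of the nuclear stain.
#' @param pixel_size_um calibration (> 0).
#' @param expected_diameter_um typical nuclear diameter (default 6.5 um).
#' @param islet_masks optional list of islet objects from [detect_islets()].
#' @param min_area_um2 nuclei smaller than this are dropped as debris.
#' @return list with `labels` (integer matrix, one label per nucleus) and
#'   `info` (`data.table`: nucleus_id, centroid, area_um2, in_islet,
#'   islet_id).
#' @export
detect_nuclei <- function(nuclear_plane, pixel_size_um,
                          expected_diameter_um = 6.5, islet_masks = NULL,
                          min_area_um2 = 8, tag_dilation_um = 5) {
  stopifnot(is.matrix(nuclear_plane), pixel_size_um > 0,
            expected_diameter_um > 0)
  d_px <- expected_diameter_um / pixel_size_um
  sm <- gaussian_blur(nuclear_plane, sigma_px = max(1, d_px / 8))
  if (max(sm) <= min(sm)) {
    warning("blank nuclear plane; no nuclei detected")
    return(empty_nuclei(dim(nuclear_plane)))
  }
  # foreground from the raw plane (sharp boundaries, unbiased areas);
  # the lightly smoothed plane provides stable seeds and watershed relief
  thr <- otsu_threshold(nuclear_plane)
  fg <- matrix(as.integer(nuclear_plane >= thr), nrow(sm))
  peaks <- local_maxima(sm, min_distance_px = max(2, 0.6 * d_px),
                        abs_threshold = thr)
  peaks <- peaks[fg[peaks] == 1L, , drop = FALSE]
  if (nrow(peaks) == 0) {
    warning("no nuclear blobs detected")
    return(empty_nuclei(dim(nuclear_plane)))
  }
  seeds <- matrix(0L, nrow(sm), ncol(sm))
  seeds[peaks] <- seq_len(nrow(peaks))
  labels <- .watershed_seeded(-sm, seeds, fg)
  labels <- merge_ridge_splits(labels, .dist_to_zero(fg))
  areas <- label_areas(labels)
  cents <- label_centroids(labels)
  keep <- which(px_to_um2(areas, pixel_size_um) >= min_area_um2)
  relab <- integer(max(labels))
  relab[keep] <- seq_along(keep)
  labels[labels > 0L] <- relab[labels[labels > 0L]]
  info <- data.table::data.table(
    nucleus_id = seq_along(keep),
    centroid_row_px = cents[keep, 1], centroid_col_px = cents[keep, 2],
    nucleus_area_um2 = px_to_um2(areas[keep], pixel_size_um))
  info$islet_id <- 0L
  if (!is.null(islet_masks) && length(islet_masks)) {
    # a nucleus belongs to an islet when it overlaps the islet tissue
    # dilated by one cell-expansion radius: dim marker-negative cells at
    # the islet margin are islet cells even though their own pixels fall
    # below the detection threshold
    d_px <- tag_dilation_um / pixel_size_um
    for (isl in islet_masks) {
      m <- matrix(0L, nrow(labels), ncol(labels))
      m[isl$pixels] <- 1L
      m <- .dilate_disk(m, d_px)
      hit <- unique(labels[m == 1L & labels > 0L])
      info$islet_id[info$nucleus_id %in% hit] <- isl$islet_id
    }
  }
  info$in_islet <- info$islet_id > 0L
  list(labels = labels, info = info)
}

# Stained-tissue support mask from the summed (background-subtracted)
# marker channels: pixels above the robust background noise floor,
# estimated by median + 6 * MAD over the non-islet region (background
# dominates there; dim exocrine tissue is a minority and MAD shrugs it
# off). In the noiseless limit the floor is 0 and support is exactly the
# painted tissue.
tissue_support <- function(s, outside) {
  v <- s[outside]
  if (length(v) < 100) v <- as.numeric(s)
  floor_ <- median(v) + 6 * stats::mad(v)
  s > floor_
}

# Merge watershed fragments that are separated by no real valley. The
# criterion lives on the foreground distance map: a fragment boundary that
# crosses the middle of an elongated nucleus is as deep as the ridge
# itself (over-split -> merge), while the boundary between genuinely
# touching nuclei runs through their narrow waist, several pixels
# shallower than either nucleus centre (keep).
merge_ridge_splits <- function(labels, sm, depth_px = 1.6) {
  n <- max(labels)
  if (n < 2L) return(labels)
  nr <- nrow(labels); nc <- ncol(labels)
  pair_tab <- list()
  collect <- function(a, b, va, vb) {
    sel <- a > 0L & b > 0L & a != b
    if (!any(sel)) return(NULL)
    lo <- pmin(a[sel], b[sel]); hi <- pmax(a[sel], b[sel])
    data.frame(key = lo * (n + 1) + hi, saddle = pmin(va[sel], vb[sel]))
  }
  pair_tab[[1]] <- collect(labels[, -nc], labels[, -1],
                           sm[, -nc], sm[, -1])
  pair_tab[[2]] <- collect(labels[-nr, ], labels[-1, ],
                           sm[-nr, ], sm[-1, ])
  pt <- do.call(rbind, pair_tab)
  if (is.null(pt) || nrow(pt) == 0) return(labels)
  saddle <- tapply(pt$saddle, pt$key, max)
  peaks <- tapply(sm[labels > 0L], labels[labels > 0L], max)
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (k in seq_along(saddle)) {
    key <- as.numeric(names(saddle)[k])
    a <- key %/% (n + 1); b <- key %% (n + 1)
    if (saddle[k] >= min(peaks[[as.character(a)]],
                         peaks[[as.character(b)]]) - depth_px) {
      ra <- find(a); rb <- find(b)
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  root <- vapply(seq_len(n), find, numeric(1))
  compact <- match(root, sort(unique(root)))  # contiguous relabelling
  labels[labels > 0L] <- compact[labels[labels > 0L]]
  labels
}

empty_nuclei <- function(dims) {
  list(labels = matrix(0L, dims[1], dims[2]),
       info = data.table::data.table(nucleus_id = integer(0),
                                     centroid_row_px = numeric(0),
                                     centroid_col_px = numeric(0),
                                     nucleus_area_um2 = numeric(0),
                                     islet_id = integer(0),
                                     in_islet = logical(0)))
}

#' Expand nuclei into cell masks
#'
#' Each nucleus grows geodesically up to `max_expansion_um` (default 5 um,
#' the usual single-cell expansion convention); contested pixels go to the
#' nearest nucleus (Voronoi rule, enforced by multi-source shortest-path
#' growth). Endocrine-candidate nuclei are clipped to the islet mask;
#' extra-islet nuclei grow only outside the islet masks. Every cell mask
#' contains its nucleus and the masks are pairwise disjoint.
#'
#' @param nuclei result of [detect_nuclei()].
#' @param islet_masks list of islet objects (may be `NULL`).
#' @param pixel_size_um calibration.
#' @param max_expansion_um maximal geodesic expansion distance.
#' @param support_mask optional logical matrix of stained-tissue pixels
#'   (e.g. summed marker channels above the islet-detection threshold);
#'   when given, cytoplasm expansion is confined to supported pixels, so
#'   cell masks follow the visible cell footprint instead of flooding
#'   unstained interstitial space. Nucleus pixels are always kept.
#' @return integer label matrix of cell masks (same labels as the nuclei).
#' @export
expand_cells <- function(nuclei, islet_masks = NULL, pixel_size_um = 0.5,
                         max_expansion_um = 5, support_mask = NULL) {
  labels <- nuclei$labels
  if (max(labels) == 0L) return(labels)
  d_px <- max_expansion_um / pixel_size_um
  dims <- dim(labels)
  sup <- if (is.null(support_mask)) matrix(TRUE, dims[1], dims[2])
         else support_mask
  if (is.null(islet_masks) || length(islet_masks) == 0) {
    con <- matrix(as.integer(sup), dims[1]); con[labels > 0L] <- 1L
    return(.grow_labels(labels, d_px, con,
                        !is.null(support_mask)))
  }
  inmask <- islet_union_mask(islet_masks, dims)
  # endocrine candidates are clipped to the islet mask plus a one-expansion
  # margin (so dim marginal islet cells keep their visible cytoplasm);
  # exocrine candidates stay outside the core mask. Nucleus pixels are
  # always traversable.
  inwide <- .dilate_disk(matrix(as.integer(inmask), dims[1]), d_px) == 1L
  in_ids <- nuclei$info$nucleus_id[nuclei$info$in_islet]
  seeds_in <- labels; seeds_in[!(seeds_in %in% in_ids)] <- 0L
  seeds_out <- labels; seeds_out[seeds_out %in% in_ids] <- 0L
  con_in <- matrix(as.integer(inwide & sup), dims[1])
  con_in[seeds_in > 0L] <- 1L
  con_out <- matrix(as.integer(!inmask & sup), dims[1])
  con_out[seeds_out > 0L] <- 1L
  g_in <- .grow_labels(seeds_in, d_px, con_in, TRUE)
  g_out <- .grow_labels(seeds_out, d_px, con_out, TRUE)
  out <- g_in
  out[g_in == 0L] <- g_out[g_in == 0L]
  out
}

#' Measure cells: per-channel means, areas, N/C ratio
#'
#' Mean intensity per channel over each cell mask; nucleus and cytoplasm
#' areas in um^2 (cytoplasm = cell minus nucleus); `nc_ratio` = nucleus /
#' cytoplasm area. Cells whose mask lost its nucleus entirely are excluded.
#'
#' @param cell_labels integer label matrix from [expand_cells()].
#' @param nuclei result of [detect_nuclei()].
#' @param image background-subtracted, aligned `islet_image`.
#' @param channels channels to quantify (default: all but first).
#' @return per-cell `data.table` with areas, `nc_ratio`, `islet_id`,
#'   `in_islet` and `mean_<channel>` / `rfu_<channel>` columns.
#' @export
measure_cells <- function(cell_labels, nuclei, image,
                          channels = image$channel_names[-1]) {
  stopifnot(inherits(image, "islet_image"))
  n <- max(cell_labels)
  if (n == 0L)
    return(data.table::data.table(cell_id = integer(0)))
  cell_px <- label_areas(cell_labels)
  nuc_px <- tabulate(nuclei$labels[nuclei$labels > 0L], nbins = n)
  if (any(cell_px == 0 & seq_len(n) %in% nuclei$info$nucleus_id))
    stop("cell mask with zero pixels")
  px <- image$pixel_size_um
  tab <- data.table::data.table(
    cell_id = seq_len(n),
    cell_area_um2 = px_to_um2(cell_px, px),
    nucleus_area_um2 = px_to_um2(nuc_px, px),
    cytoplasm_area_um2 = px_to_um2(cell_px - nuc_px, px))
  tab$nc_ratio <- ifelse(tab$cytoplasm_area_um2 > 0,
                         tab$nucleus_area_um2 / tab$cytoplasm_area_um2, NA_real_)
  idx <- which(cell_labels > 0L)
  l <- cell_labels[idx]
  full <- 2^image$bit_depth - 1
  for (ch in channels) {
    v <- image$planes[[ch]][idx]
    s <- rowsum(v, l)
    mean_ch <- rep(NA_real_, n)
    mean_ch[as.integer(rownames(s))] <- s[, 1] /
      cell_px[as.integer(rownames(s))]
    tab[[paste0("mean_", ch)]] <- mean_ch
    tab[[paste0("rfu_", ch)]] <- mean_ch / full
  }
  info <- nuclei$info
  tab$islet_id <- info$islet_id[match(tab$cell_id, info$nucleus_id)]
  tab$in_islet <- info$in_islet[match(tab$cell_id, info$nucleus_id)]
  tab$centroid_row_px <- info$centroid_row_px[match(tab$cell_id, info$nucleus_id)]
  tab$centroid_col_px <- info$centroid_col_px[match(tab$cell_id, info$nucleus_id)]
  tab$nucleated <- nuc_px > 0
  tab[cell_px > 0]
}

#' Derive a per-channel positivity threshold from cell mean intensities
#'
#' Default method: Otsu over the distribution of per-cell mean intensities
#' for the channel (per staining batch). A fixed manual threshold can be
#' supplied instead. A degenerate (near-constant) distribution is an error
#' advising a manual threshold.
#'
#' @param cells per-cell table from [measure_cells()].
#' @param channel channel name.
#' @param method `"otsu"` or `"manual"`.
#' @param value manual threshold when `method = "manual"`.
#' @param min_fold minimum fold separation between the class means for the
#'   Otsu cut to be accepted; below it the distribution is treated as
#'   all-negative and `+Inf` is returned with a warning.
#' @return threshold (numeric scalar).
#' @export
determine_cell_thresholds <- function(cells, channel, method = c("otsu", "manual"),
                                      value = NULL, min_fold = 3) {
  method <- match.arg(method)
  if (method == "manual") {
    if (is.null(value)) stop("manual method needs 'value'")
    return(value)
  }
  col <- paste0("mean_", channel)
  if (!col %in% names(cells)) stop("no measured channel '", channel, "'")
  v <- cells[[col]]
  v <- v[is.finite(v)]
  if (length(v) < 20)
    stop("need >= 20 cells to derive a threshold for '", channel, "'")
  if (var(v) < 1e-12 * max(1, mean(v)^2))
    stop("cell mean intensity distribution for '", channel,
         "' is degenerate; supply a manual threshold")
  thr <- as.numeric(otsu_threshold(v))
  # a genuine positive population sits several-fold above the negative
  # state; a unimodal (all-negative) distribution would otherwise be cut
  # in half by Otsu, fabricating positives
  lo <- mean(v[v < thr]); hi <- mean(v[v >= thr])
  if (!is.finite(lo) || !is.finite(hi) || hi < min_fold * lo) {
    warning("cell means for '", channel, "' show no separable positive ",
            "population; returning +Inf (all cells negative). Supply a ",
            "manual or cohort-pooled threshold if positives are expected.")
    return(Inf)
  }
  thr
}

#' Classify cells by combining per-marker thresholds
#'
#' A cell is positive for a marker when its mean intensity is at or above
#' the marker threshold (ties count positive). The 2^k flag combinations
#' partition all cells; a readable class label
#' (`"negative"`, `"INS+"`, `"INS+PC13+"`, ...) is derived from the flags.
#'
#' @param cells per-cell table from [measure_cells()].
#' @param thresholds named numeric, one entry per marker channel.
#' @return `cells` with added logical `pos_<marker>` columns and a
#'   `phenotype` column.
#' @export
classify_cells <- function(cells, thresholds) {
  if (is.null(names(thresholds)) || any(!nzchar(names(thresholds))))
    stop("thresholds must be a named vector of marker channels")
  for (m in names(thresholds)) {
    col <- paste0("mean_", m)
    if (!col %in% names(cells))
      stop("missing measured channel for threshold: ", m)
    cells[[paste0("pos_", m)]] <- cells[[col]] >= thresholds[[m]]
  }
  flags <- as.matrix(cells[, paste0("pos_", names(thresholds)), with = FALSE])
  lab <- apply(flags, 1, function(f) {
    if (!any(f)) "negative"
    else paste0(names(thresholds)[f], "+", collapse = "")
  })
  cells$phenotype <- lab
  cells
}

#' Per-cell Manders co-localisation
#'
#' [manders_coefficients()] restricted to each cell mask. The donor-level
#' value downstream is the mean over that donor's double-positive cells.
#'
#' @param cells classified cell table (needs `pos_` flags for both
#'   channels).
#' @param cell_labels label matrix from [expand_cells()].
#' @param image background-subtracted `islet_image`.
#' @param channel_a,channel_b channel names.
#' @param threshold_a,threshold_b pixel-level positivity thresholds; when
#'   `NULL` (default) each cell gets its own Otsu threshold over the
#'   within-cell intensity distribution, which separates the punctate
#'   granule signal from the diffuse base irrespective of the cell's
#'   overall brightness.
#' @param positive_only compute only for cells positive for both markers
#'   (default TRUE; others get `NA`).
#' @return `cells` with `cell_m1_<a>_<b>` and `cell_m2_<a>_<b>` columns.
#' @export
cell_manders <- function(cells, cell_labels, image, channel_a, channel_b,
                         threshold_a = NULL, threshold_b = NULL,
                         positive_only = TRUE) {
  pa <- image$planes[[channel_a]]
  pb <- image$planes[[channel_b]]
  m1 <- rep(NA_real_, nrow(cells)); m2 <- m1
  idx_all <- split(which(cell_labels > 0L), cell_labels[cell_labels > 0L])
  want <- if (positive_only &&
              all(paste0("pos_", c(channel_a, channel_b)) %in% names(cells)))
    cells[[paste0("pos_", channel_a)]] & cells[[paste0("pos_", channel_b)]]
  else rep(TRUE, nrow(cells))
  cell_thr <- function(v, fixed) {
    if (!is.null(fixed)) return(fixed)
    # estimate the base/granule cut from in-cell signal only: mask-edge
    # pixels near zero would otherwise pull the Otsu cut below the
    # diffuse base and saturate the coefficients
    v <- v[v > 0.25 * mean(v)]
    if (length(v) < 2 || max(v) <= min(v)) return(Inf)
    as.numeric(otsu_threshold(v))
  }
  for (i in seq_len(nrow(cells))) {
    if (!isTRUE(want[i])) next
    px <- idx_all[[as.character(cells$cell_id[i])]]
    if (is.null(px)) next
    mm <- suppressWarnings(
      manders_coefficients(pa[px], pb[px], cell_thr(pa[px], threshold_a),
                           cell_thr(pb[px], threshold_b)))
    m1[i] <- mm[["M1"]]; m2[i] <- mm[["M2"]]
  }
  cells[[paste0("cell_m1_", channel_a, "_", channel_b)]] <- m1
  cells[[paste0("cell_m2_", channel_a, "_", channel_b)]] <- m2
  cells
}

#' Per-cell proinsulin/insulin intensity ratio
#'
#' Ratio of the proinsulin to insulin mean intensity for insulin-positive
#' cells (the prohormone-processing surrogate); insulin-negative cells and
#' zero insulin means are excluded (`NA`) and counted in the attribute
#' `n_excluded`. The donor-level value downstream is the median over cells.
#'
#' @param cells classified cell table with `mean_ProINS`, `mean_INS` and
#'   `pos_INS` columns.
#' @return `cells` with a `proins_ins_ratio` column.
#' @export
proinsulin_insulin_ratio <- function(cells) {
  need <- c("mean_ProINS", "mean_INS", "pos_INS")
  if (!all(need %in% names(cells)))
    stop("cells must carry mean_ProINS, mean_INS and pos_INS")
  ok <- cells$pos_INS & cells$mean_INS > 0
  cells$proins_ins_ratio <- ifelse(ok, cells$mean_ProINS / cells$mean_INS,
                                   NA_real_)
  attr(cells, "n_excluded") <- sum(!ok)
  cells
}

#' Select peri-islet exocrine cells
#'
#' Exocrine-candidate cells (outside every islet) whose centroid lies
#' within `max_distance_um` of an islet boundary, carrying the same
#' morphometry fields as islet cells.
#'
#' @param cells measured cell table.
#' @param islet_masks list of islet objects.
#' @param pixel_size_um calibration.
#' @param max_distance_um band width around the islet boundary (default 20).
#' @return subset of `cells`.
#' @export
peri_islet_exocrine_cells <- function(cells, islet_masks, pixel_size_um,
                                      max_distance_um = 20) {
  if (length(islet_masks) == 0 || nrow(cells) == 0) return(cells[0])
  dims <- islet_masks[[1]]$dims
  m <- matrix(as.integer(islet_union_mask(islet_masks, dims)), dims[1])
  band <- .dilate_disk(m, max_distance_um / pixel_size_um)
  pos <- cbind(pmin(pmax(round(cells$centroid_row_px), 1), dims[1]),
               pmin(pmax(round(cells$centroid_col_px), 1), dims[2]))
  near <- band[pos] == 1L & m[pos] == 0L
  cells[!cells$in_islet & near]
}

#' Single-cell analysis of one image
#'
#' Full single-cell arm on an aligned, background-subtracted image: nucleus
#' detection, cell expansion, measurement, per-batch Otsu thresholds,
#' classification, optional per-cell co-localisation for one channel pair,
#' and the proinsulin/insulin ratio on panel A.
#'
#' @param image processed `islet_image` (nuclear channel first).
#' @param islets list of islet objects from [detect_islets()].
#' @param marker_channels marker channels.
#' @param thresholds optional named manual thresholds (otherwise per-image
#'   Otsu on cell means).
#' @param coloc_pair 2-vector of channel names for per-cell Manders, or
#'   `NULL`.
#' @param expected_diameter_um,max_expansion_um segmentation scales.
#' @param exclude_delta drop elongated-profile (delta-like) somatostatin
#'   single-positive cells from the per-cell table; they defeat 2D
#'   segmentation and are quantified at islet level only.
#' @return per-cell `data.table`; label matrices in attributes
#'   `cell_labels` and `nuclei`.
#' @export
analyze_cells <- function(image, islets,
                          marker_channels = image$channel_names[-1],
                          thresholds = NULL, coloc_pair = NULL,
                          expected_diameter_um = 6.5, max_expansion_um = 5,
                          exclude_delta = TRUE, classify = TRUE) {
  nuc <- detect_nuclei(get_plane(image, image$channel_names[1]),
                       image$pixel_size_um, expected_diameter_um, islets)
  # stained-tissue support: marker sum above the background noise floor,
  # so expansion follows visible cell footprints rather than flooding
  # interstitial space
  s <- Reduce(`+`, image$planes[marker_channels])
  support <- if (max(s) > min(s))
    tissue_support(s, !islet_union_mask(islets, dim(s))) else NULL
  labs <- expand_cells(nuc, islets, image$pixel_size_um, max_expansion_um,
                       support_mask = support)
  cells <- measure_cells(labs, nuc, image, marker_channels)
  if (nrow(cells) == 0) return(cells)
  if (classify) {
    cells <- finalize_cells(cells, thresholds, marker_channels,
                            exclude_delta = exclude_delta)
    if (!is.null(coloc_pair))
      cells <- cell_manders(cells, labs, image, coloc_pair[1], coloc_pair[2],
                            positive_only = TRUE)
  } else if (!is.null(coloc_pair)) {
    # unclassified pass (cohort pooling): compute for every cell; the
    # caller filters on the eventual positivity flags
    cells <- cell_manders(cells, labs, image, coloc_pair[1], coloc_pair[2],
                          positive_only = FALSE)
  }
  attr(cells, "cell_labels") <- labs
  attr(cells, "nuclei") <- nuc
  cells
}

#' Classify measured cells and derive dependent read-outs
#'
#' Applies (or derives, per batch) the cell mean-intensity thresholds,
#' attaches phenotype flags and labels, optionally removes
#' somatostatin-single-positive (delta-like) cells, and computes the
#' proinsulin/insulin ratio on panel-A tables. Operates on a plain cell
#' table, so thresholds can be pooled across a whole staining batch (all
#' images of a cohort) before classification.
#'
#' @param cells measured cell table (possibly pooled over images/donors).
#' @param thresholds named numeric per marker; missing entries derived by
#'   [determine_cell_thresholds()] from this table.
#' @param marker_channels marker channel names.
#' @param exclude_delta drop SST single-positive cells (see
#'   [analyze_cells()]).
#' @return classified cell table with attribute `thresholds`.
#' @export
finalize_cells <- function(cells, thresholds = NULL, marker_channels,
                           exclude_delta = TRUE) {
  thr <- setNames(numeric(length(marker_channels)), marker_channels)
  for (ch in marker_channels) {
    thr[ch] <- if (!is.null(thresholds) && ch %in% names(thresholds))
      thresholds[[ch]]
    else tryCatch(suppressWarnings(determine_cell_thresholds(cells, ch)),
                  error = function(e) Inf)
  }
  cells <- classify_cells(cells, thr)
  if (exclude_delta && "pos_SST" %in% names(cells)) {
    sst_only <- cells$pos_SST &
      !Reduce(`|`, lapply(setdiff(marker_channels, "SST"),
                          function(m) cells[[paste0("pos_", m)]]))
    cells <- cells[!sst_only]
  }
  if (all(c("mean_ProINS", "mean_INS", "pos_INS") %in% names(cells)))
    cells <- proinsulin_insulin_ratio(cells)
  attr(cells, "thresholds") <- thr
  cells
}
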