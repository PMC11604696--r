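# Single-cell arm: nucleus detection, expansion, measurement, thresholds,
# classification, co-localisation, morphometry.

test_that("nucleus detection recovers non-touching nuclei exactly", {
  s <- render_islet_image(clean_config(), seed = 2)
  nuc <- detect_nuclei(s$image$planes$DAPI, 0.5)
  expect_identical(nrow(nuc$info), nrow(s$truth))
  # nucleus areas are recovered without bias in the noiseless limit
  expect_equal(sum(nuc$labels > 0), sum(s$nucleus_labels > 0))
  # blank plane: empty result with a warning
  expect_warning(e <- detect_nuclei(matrix(0, 50, 50), 0.5), "blank|blobs")
  expect_identical(nrow(e$info), 0L)
})

test_that("detection count survives default noise within 5%", {
  s <- render_islet_image(tiny_config(), seed = 33)
  nuc <- detect_nuclei(s$image$planes$DAPI, 0.5)
  expect_lt(abs(nrow(nuc$info) - nrow(s$truth)) / nrow(s$truth), 0.05)
})

test_that("watershed splits two slightly overlapping nuclei", {
  plane <- matrix(0, 60, 60)
  plane <- paint_disk(plane, 30, 25, 6.5, 15000)
  plane <- paint_disk(plane, 30, 36, 6.5, 15000)  # overlap < 20% of area
  nuc <- detect_nuclei(plane, pixel_size_um = 0.5, expected_diameter_um = 6.5)
  expect_identical(nrow(nuc$info), 2L)
  a <- nuc$info$nucleus_area_um2
  expect_lt(abs(a[1] - a[2]) / mean(a), 0.3)
})

test_that("cell expansion: disk growth, Voronoi sharing, containment", {
  labs0 <- matrix(0L, 80, 80)
  labs0 <- {m <- labs0; m[36:44, 36:44] <- 1L; m}  # 9x9 square nucleus
  nuc <- list(labels = labs0,
              info = data.table::data.table(nucleus_id = 1L,
                                            centroid_row_px = 40,
                                            centroid_col_px = 40,
                                            nucleus_area_um2 = 81 * 0.25,
                                            islet_id = 0L, in_islet = FALSE))
  grown <- expand_cells(nuc, NULL, pixel_size_um = 0.5, max_expansion_um = 5)
  expect_true(all(grown[labs0 == 1L] == 1L))
  # geodesic disk growth: area close to the euclidean dilation (chamfer
  # metric overestimates distances by <= ~8%)
  target <- sum(isletquant:::.dilate_disk(labs0, 10))
  expect_lt(abs(sum(grown == 1L) - target) / target, 0.08)

  # two nuclei: contested pixels split at the equidistant line
  labs2 <- matrix(0L, 60, 80)
  labs2[28:32, 28:32] <- 1L
  labs2[28:32, 44:48] <- 2L   # 8 um apart (16 px), 5 um expansion
  nuc2 <- list(labels = labs2,
               info = data.table::data.table(nucleus_id = c(1L, 2L),
                                             centroid_row_px = c(30, 30),
                                             centroid_col_px = c(30, 46),
                                             nucleus_area_um2 = c(6.25, 6.25),
                                             islet_id = c(0L, 0L),
                                             in_islet = c(FALSE, FALSE)))
  g2 <- expand_cells(nuc2, NULL, 0.5, 5)
  expect_true(all(g2[30, 34:37] == 1L))
  expect_true(all(g2[30, 39:42] == 2L))
  # near-symmetric split (discrete tie-breaks allow a ~2% imbalance)
  expect_lt(abs(sum(g2 == 1L) - sum(g2 == 2L)) / sum(g2 > 0L), 0.05)
  # empty input -> empty output
  e <- expand_cells(list(labels = matrix(0L, 10, 10),
                         info = data.table::data.table()), NULL, 0.5, 5)
  expect_identical(max(e), 0L)
})

test_that("measure_cells computes means, areas and N/C by convention", {
  cell <- matrix(0L, 40, 40); cell[11:26, 11:30] <- 1L  # 320 px cell
  nucm <- matrix(0L, 40, 40); nucm[15:22, 15:24] <- 1L  # 80 px nucleus
  img <- multichannel_image(list(DAPI = matrix(0, 40, 40),
                                 INS = matrix(100, 40, 40)),
                            pixel_size_um = 0.5)
  nuc <- list(labels = nucm,
              info = data.table::data.table(nucleus_id = 1L,
                                            centroid_row_px = 18,
                                            centroid_col_px = 19,
                                            nucleus_area_um2 = 20,
                                            islet_id = 0L, in_islet = FALSE))
  tab <- measure_cells(cell, nuc, img, channels = "INS")
  expect_equal(tab$mean_INS, 100)
  expect_equal(tab$cell_area_um2, 80)        # 320 px * 0.25
  expect_equal(tab$nucleus_area_um2, 20)     # 80 px * 0.25
  expect_equal(tab$cytoplasm_area_um2, 60)
  expect_equal(tab$nc_ratio, 20 / 60)
})

test_that("cytoplasm areas track ground truth on a synthetic scene", {
  s <- render_islet_image(clean_config(exocrine_fill = 0.4), seed = 19)
  ires <- analyze_islets(s$image)
  cells <- analyze_cells(attr(ires, "image"), attr(ires, "islets"),
                         thresholds = c(INS = 3000, ProINS = 3000,
                                        PC13 = 3000))
  pos <- cbind(round(cells$centroid_row_px), round(cells$centroid_col_px))
  cells$truth_id <- s$cell_labels[pos]
  m <- merge(cells, s$truth, by.x = "truth_id", by.y = "cell_id")
  expect_gte(nrow(m), 15)
  expect_gt(cor(m$cytoplasm_area_um2.x, m$cytoplasm_area_um2.y), 0.9)
})

test_that("cell thresholds: Otsu on the cell-mean distribution", {
  set.seed(61)
  cells <- data.table::data.table(
    mean_X = c(rnorm(150, 20, 5), rnorm(100, 150, 20)),
    truth = rep(c(FALSE, TRUE), c(150, 100)))
  thr <- determine_cell_thresholds(cells, "X")
  # the between-class criterion is flat across the empty gap and lands at
  # its lower edge (~35; confirmed by the exhaustive oracle below)
  expect_gt(thr, 30); expect_lt(thr, 120)
  acc <- mean((cells$mean_X >= thr) == cells$truth)
  expect_gte(acc, 0.98)
  # equals the exhaustive between-class-variance maximiser
  lvl <- attr(otsu_threshold(cells$mean_X), "level")
  expect_identical(lvl, bf_otsu_level(cells$mean_X))
  # manual override and degenerate guards
  expect_equal(determine_cell_thresholds(cells, "X", "manual", value = 50), 50)
  flat <- data.table::data.table(mean_X = rep(7, 30))
  expect_error(determine_cell_thresholds(flat, "X"), "degenerate")
  expect_error(determine_cell_thresholds(cells[1:5], "X"), ">= 20")
  # unimodal distribution: no fabricated positives
  uni <- data.table::data.table(mean_X = rlnorm(200, log(600), 0.3))
  expect_warning(t_inf <- determine_cell_thresholds(uni, "X"), "no separable")
  expect_identical(t_inf, Inf)
})

test_that("classification combines marker flags into phenotypes", {
  cells <- data.table::data.table(
    mean_INS = c(200, 10, 200, 10), mean_ProINS = c(180, 5, 5, 5),
    mean_PC13 = c(150, 8, 8, 200))
  out <- classify_cells(cells, c(INS = 50, ProINS = 50, PC13 = 50))
  expect_identical(out$phenotype,
                   c("INS+ProINS+PC13+", "negative", "INS+", "PC13+"))
  expect_error(classify_cells(cells, c(INS = 50, ProINS = 50, GCG = 50)),
               "GCG")
  # ties at the threshold count as positive
  tie <- classify_cells(data.table::data.table(mean_INS = 50), c(INS = 50))
  expect_true(tie$pos_INS)
})

test_that("raising a threshold never increases the positive count", {
  set.seed(8)
  cells <- data.table::data.table(mean_X = rlnorm(300, 7, 1))
  counts <- vapply(seq(100, 5000, length.out = 20), function(t)
    sum(classify_cells(data.table::copy(cells), c(X = t))$pos_X), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("phenotype classes partition all cells", {
  s <- render_islet_image(tiny_config(), seed = 51)
  ires <- analyze_islets(s$image)
  cells <- analyze_cells(attr(ires, "image"), attr(ires, "islets"),
                         thresholds = c(INS = 3000, ProINS = 3000,
                                        PC13 = 3000))
  expect_identical(sum(table(cells$phenotype)), nrow(cells))
  flags <- as.matrix(cells[, c("pos_INS", "pos_ProINS", "pos_PC13")])
  derived <- apply(flags, 1, function(f)
    if (!any(f)) "negative"
    else paste0(c("INS", "ProINS", "PC13")[f], "+", collapse = ""))
  expect_identical(cells$phenotype, unname(derived))
})

test_that("per-cell Manders: closed forms and generator expectation", {
  # constructed single cell with identical / disjoint channels
  lab <- matrix(0L, 30, 30); lab[10:20, 10:20] <- 1L
  a <- matrix(0, 30, 30); a[10:20, 10:15] <- 100
  b1 <- a
  b2 <- matrix(0, 30, 30); b2[10:20, 16:20] <- 100
  img1 <- multichannel_image(list(A = a, B = b1), pixel_size_um = 0.5)
  img2 <- multichannel_image(list(A = a, B = b2), pixel_size_um = 0.5)
  cells <- data.table::data.table(cell_id = 1L)
  r1 <- cell_manders(data.table::copy(cells), lab, img1, "A", "B",
                     threshold_a = 50, threshold_b = 50,
                     positive_only = FALSE)
  expect_equal(r1$cell_m1_A_B, 1); expect_equal(r1$cell_m2_A_B, 1)
  r2 <- cell_manders(data.table::copy(cells), lab, img2, "A", "B",
                     threshold_a = 50, threshold_b = 50,
                     positive_only = FALSE)
  expect_equal(r2$cell_m1_A_B, 0); expect_equal(r2$cell_m2_A_B, 0)

  # granule-sharing model: mean per-cell M1 ~ coloc_fraction 0.8
  s <- render_islet_image(tiny_config(coloc_fraction = c("INS:PC13" = 0.8)),
                          seed = 13)
  ires <- analyze_islets(s$image)
  out <- analyze_cells(attr(ires, "image"), attr(ires, "islets"),
                       coloc_pair = c("INS", "PC13"),
                       thresholds = c(INS = 3000, ProINS = 3000, PC13 = 3000))
  expect_lt(abs(mean(out$cell_m1_INS_PC13, na.rm = TRUE) - 0.8), 0.05)
})

test_that("proinsulin/insulin ratio per cell and donor median", {
  cells <- data.table::data.table(mean_ProINS = c(50, 80, 10),
                                  mean_INS = c(100, 80, 0),
                                  pos_INS = c(TRUE, TRUE, FALSE))
  out <- proinsulin_insulin_ratio(cells)
  expect_equal(out$proins_ins_ratio, c(0.5, 1.0, NA))
  expect_identical(attr(out, "n_excluded"), 1L)
  # generator with proportional scale 0.8
  s <- render_islet_image(tiny_config(proins_ins_ratio = 0.8), seed = 27)
  ires <- analyze_islets(s$image)
  cells2 <- analyze_cells(attr(ires, "image"), attr(ires, "islets"),
                          thresholds = c(INS = 3000, ProINS = 3000,
                                         PC13 = 3000))
  expect_lt(abs(median(cells2$proins_ins_ratio, na.rm = TRUE) - 0.8), 0.05)
})

test_that("peri-islet exocrine selection respects the distance band", {
  cells <- data.table::data.table(
    cell_id = 1:2, in_islet = c(FALSE, FALSE),
    centroid_row_px = c(30, 30), centroid_col_px = c(60, 115),
    cytoplasm_area_um2 = c(90, 90))
  m <- matrix(FALSE, 60, 160); m[20:40, 20:50] <- TRUE
  islets <- list(list(islet_id = 1L, pixels = which(m), dims = c(60L, 160L),
                      area_um2 = sum(m) * 0.25))
  # 5 um outside the boundary -> included; 32.5 um outside -> excluded
  near <- peri_islet_exocrine_cells(cells, islets, pixel_size_um = 0.5,
                                    max_distance_um = 20)
  expect_identical(near$cell_id, 1L)
})

test_that("peri-islet exocrine morphometry recovers the preset", {
  # narrow exocrine size spread (cv 0.12) so ~40 peri-islet cells pin the
  # mean within the 10% recovery tolerance (3 SE ~ 6%)
  morph <- isletquant:::default_morphology()
  morph$cytoplasm_area_um2$exocrine <- list(mean = 95.76, cv = 0.12)
  got <- numeric(0)
  for (sd_ in 1:10) {
    s <- render_islet_image(
      generator_config(image_shape_px = c(448L, 448L), n_islets = 1L,
                       cells_per_islet = list(mean = 14, dispersion = 1e6),
                       morphology = morph,
                       exocrine_fill = 0.8), seed = sd_)
    ires <- analyze_islets(s$image)
    cells <- analyze_cells(attr(ires, "image"), attr(ires, "islets"),
                           thresholds = c(INS = 3000, ProINS = 3000,
                                          PC13 = 3000))
    peri <- peri_islet_exocrine_cells(cells, attr(ires, "islets"), 0.5, 20)
    got <- c(got, peri$cytoplasm_area_um2)
  }
  expect_gt(length(got), 20)
  expect_lt(abs(mean(got) - 95.76) / 95.76, 0.10)
})

test_that("delta-like SST single-positive cells are excluded by default", {
  cells <- data.table::data.table(
    mean_GCG = c(10, 10, 9000), mean_SST = c(9000, 10, 10),
    mean_PC13 = c(10, 9000, 9000))
  thr <- c(GCG = 3000, SST = 3000, PC13 = 3000)
  kept <- finalize_cells(data.table::copy(cells), thr, names(thr),
                         exclude_delta = TRUE)
  expect_identical(nrow(kept), 2L)
  all3 <- finalize_cells(data.table::copy(cells), thr, names(thr),
                         exclude_delta = FALSE)
  expect_identical(nrow(all3), 3L)
})
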