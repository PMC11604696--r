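# Whole-islet arm: alignment, illumination correction, detection,
# background subtraction, measurement, Manders.

test_that("align_channels recovers constructed integer shifts", {
  set.seed(12)
  ref <- gaussian_blur(matrix(runif(120 * 120), 120), 2)
  shifted <- isletquant:::roll_matrix(ref, 2, -1)
  img <- multichannel_image(list(a = ref, b = shifted, c = ref),
                            pixel_size_um = 0.5)
  out <- align_channels(img, "a")
  expect_identical(unname(attr(out, "shifts")["b", ]), c(-2L, 1L))
  expect_equal(out$planes$b, ref)
  expect_identical(unname(attr(out, "shifts")["c", ]), c(0L, 0L))
  # implausible shifts are refused with identity fallback
  far <- isletquant:::roll_matrix(ref, 30, 0)
  img2 <- multichannel_image(list(a = ref, b = far), pixel_size_um = 0.5)
  expect_warning(out2 <- align_channels(img2, "a", max_shift_px = 10),
                 "exceeds")
  expect_equal(out2$planes$b, far)
})

test_that("alignment restores co-localisation on shifted generator output", {
  cfg <- tiny_config(channel_shift_px = c(0L, 0L, 0L, 3L))
  s <- render_islet_image(cfg, seed = 6)
  img0 <- s$image
  imgA <- align_channels(img0, reference_channel = "INS",
                         channels = c("INS", "ProINS", "PC13"))
  expect_identical(unname(attr(imgA, "shifts")["PC13", ]), c(-3L, -3L))
  m_pre <- manders_coefficients(as.numeric(img0$planes$INS),
                                as.numeric(img0$planes$PC13), 5000, 5000)
  m_post <- manders_coefficients(as.numeric(imgA$planes$INS),
                                 as.numeric(imgA$planes$PC13), 5000, 5000)
  expect_gte(m_post[["M1"]], m_pre[["M1"]])
})

test_that("illumination correction flattens a linear gradient", {
  # field scale must sit between cell diameter and gradient scale
  base <- matrix(100, 200, 200)
  grad <- outer(rep(1, 200), seq(0.8, 1.2, length.out = 200))
  plane <- base * grad
  out <- correct_illumination(plane, smoothing_scale_um = 15,
                              pixel_size_um = 0.5)
  expect_equal(mean(out), mean(plane), tolerance = 1e-3)
  cv <- function(m) sd(m) / mean(m)
  expect_gt(cv(plane) / cv(out), 5)
  # constant plane is a fixed point
  const <- matrix(7, 50, 50)
  expect_equal(correct_illumination(const, 50, 0.5), const)
  # near-zero field floors with a warning
  z <- matrix(0, 60, 60); z[1, 1] <- 1
  expect_warning(correct_illumination(z, 1, 0.5), "floor")
})

test_that("generator illumination gradient is corrected to a flat field", {
  # tissue-free field isolates the gradient itself; self-division is only
  # valid without dominant sparse bright structures (see vignette)
  cfg <- tiny_config(illumination_gradient_amplitude = 0.2, noise_sd = 0,
                     n_islets = 0L, exocrine_fill = 0)
  s <- render_islet_image(cfg, seed = 8)
  bg0 <- s$image$planes$DAPI
  out <- correct_illumination(bg0, smoothing_scale_um = 25,
                              pixel_size_um = 0.5)
  gr <- function(m) abs(median(m[, 1:20]) - median(m[, 301:320])) /
    median(m)
  expect_gt(gr(bg0), 0.05)      # the gradient is visible before
  expect_lt(gr(out), 0.02)      # and flat after
})

test_that("detect_islets finds exactly the generated islets (noiseless)", {
  cfg <- generator_config(image_shape_px = c(448L, 448L), n_islets = 3L,
                          cells_per_islet = list(mean = 12, dispersion = 1e6),
                          marker_models = visible_models_A(),
                          exocrine_fill = 0.3, noise_sd = 0,
                          background_level = 0,
                          illumination_gradient_amplitude = 0)
  s <- render_islet_image(cfg, seed = 14)
  islets <- detect_islets(s$image, c("INS", "ProINS", "PC13"))
  expect_identical(length(islets), 3L)
  # each detected mask covers >= 95% of its ground-truth islet pixels
  dm <- dim(s$cell_labels)
  for (i in 1:3) {
    ids <- s$truth$cell_id[s$truth$islet_id == i]
    tmask <- matrix(s$cell_labels %in% ids, dm[1])
    cov <- vapply(islets, function(isl) {
      m <- matrix(FALSE, dm[1], dm[2]); m[isl$pixels] <- TRUE
      sum(m & tmask) / sum(tmask)
    }, numeric(1))
    expect_gte(max(cov), 0.95)
  }
  # masks are pairwise disjoint and areas are exact pixel counts
  all_px <- unlist(lapply(islets, `[[`, "pixels"))
  expect_false(anyDuplicated(all_px) > 0)
  for (isl in islets)
    expect_equal(isl$area_um2, length(isl$pixels) * 0.25)
})

test_that("blank images give an empty islet list", {
  img <- multichannel_image(list(DAPI = matrix(0, 64, 64),
                                 INS = matrix(0, 64, 64)),
                            pixel_size_um = 0.5)
  expect_identical(detect_islets(img, "INS"), list())
})

test_that("clusters below the min-cell area floor are excluded", {
  # controlled cell size (110 um^2, cv 5%): 9 cells ~ 990 um^2 falls below
  # the 10-cell floor of 1200 um^2, the full 12-cell islet stays above
  morph <- isletquant:::default_morphology()
  for (ct in c("beta", "alpha", "delta", "exocrine")) {
    morph$cytoplasm_area_um2[[ct]] <- list(mean = 80, cv = 0.05)
    morph$nucleus_area_um2[[ct]] <- list(mean = 30, cv = 0.05)
  }
  cfg <- generator_config(image_shape_px = c(320L, 320L), n_islets = 1L,
                          cells_per_islet = list(mean = 12, dispersion = 1e6),
                          marker_models = visible_models_A(),
                          morphology = morph,
                          exocrine_fill = 0, noise_sd = 0,
                          background_level = 0,
                          illumination_gradient_amplitude = 0)
  s <- render_islet_image(cfg, seed = 18)
  expect_identical(length(detect_islets(s$image, c("INS", "ProINS", "PC13"),
                                        min_cells = 10L)), 1L)
  # surgical fixture: erase outermost cells until 9 remain -> excluded at
  # min_cells=10 (outermost keeps the survivors connected)
  img9 <- s$image
  tr <- s$truth[s$truth$islet_id == 1]
  d <- sqrt((tr$centroid_row_px - mean(tr$centroid_row_px))^2 +
              (tr$centroid_col_px - mean(tr$centroid_col_px))^2)
  drop <- tr$cell_id[order(-d)][seq_len(nrow(tr) - 9L)]
  for (ch in c("INS", "ProINS", "PC13"))
    img9$planes[[ch]][s$cell_labels %in% drop] <- 0
  expect_identical(length(detect_islets(img9, c("INS", "ProINS", "PC13"),
                                        min_cells = 10L)), 0L)
  expect_identical(length(detect_islets(img9, c("INS", "ProINS", "PC13"),
                                        min_cells = 1L)), 1L)
})

test_that("background subtraction removes the additive offset", {
  img <- multichannel_image(list(DAPI = matrix(50, 80, 80),
                                 INS = matrix(50, 80, 80)),
                            pixel_size_um = 0.5)
  img$planes$INS[30:50, 30:50] <- 250
  islet <- list(list(islet_id = 1L,
                     pixels = which(img$planes$INS == 250),
                     dims = c(80L, 80L), area_um2 = 21^2 * 0.25))
  out <- subtract_background(img, islet)
  expect_equal(unname(attr(out, "background")[["INS"]]), 50)
  expect_true(all(out$planes$INS[30:50, 30:50] == 200))
  expect_equal(median(out$planes$INS[-(which(img$planes$INS == 250))]), 0)
  # zero background leaves the image unchanged
  img0 <- multichannel_image(list(INS = matrix(0, 40, 40)), pixel_size_um = 1)
  img0$planes$INS[10:20, 10:20] <- 100
  isl0 <- list(list(islet_id = 1L, pixels = which(img0$planes$INS == 100),
                    dims = c(40L, 40L), area_um2 = 1))
  expect_equal(subtract_background(img0, isl0)$planes$INS, img0$planes$INS)
  # full-cover masks make the background undefined
  full <- list(list(islet_id = 1L, pixels = seq_len(40 * 40),
                    dims = c(40L, 40L), area_um2 = 400))
  expect_error(subtract_background(img0, full), "undefined")
})

test_that("generator background is removed to below the noise level", {
  cfg <- tiny_config(background_level = 400, noise_sd = 60)
  s <- render_islet_image(cfg, seed = 23)
  islets <- detect_islets(s$image, c("INS", "ProINS", "PC13"))
  out <- subtract_background(s$image, islets)
  outside <- !isletquant:::islet_union_mask(islets, dim(s$cell_labels))
  expect_lt(median(out$planes$INS[outside]), 60)
})

test_that("measure_islet boundary cases and area-fraction recovery", {
  img <- multichannel_image(list(DAPI = matrix(0, 60, 60),
                                 A = matrix(100, 60, 60),
                                 B = matrix(0, 60, 60)),
                            pixel_size_um = 0.5)
  islet <- list(islet_id = 1L, pixels = which(matrix(TRUE, 60, 60))[1:900],
                dims = c(60L, 60L), area_um2 = 225)
  row <- measure_islet(islet, img, channels = c("A", "B"),
                       thresholds = c(A = 50, B = 50))
  expect_equal(row$frac_A, 1.0)
  expect_equal(row$frac_B, 0.0)
  expect_equal(row$mean_B, 0)
  expect_error(measure_islet(list(islet_id = 1, pixels = integer(0),
                                  dims = c(60L, 60L)), img), "empty")
})

test_that("occupied area fraction recovers the configured positive share", {
  # 40% of uniformly sized islet cells glucagon-positive
  mm <- isletquant:::default_marker_models("B")
  mm$alpha$GCG$p_pos <- 1; mm$alpha$SST$p_pos <- 0; mm$alpha$PC13$p_pos <- 1
  mm$beta$GCG$p_pos <- 0; mm$beta$PC13$p_pos <- 1
  morph <- isletquant:::default_morphology()
  for (ct in c("beta", "alpha", "delta", "exocrine")) {
    morph$cytoplasm_area_um2[[ct]] <- list(mean = 87, cv = 0.05)
    morph$nucleus_area_um2[[ct]] <- list(mean = 30, cv = 0.05)
  }
  cfg <- generator_config(panel = "B", image_shape_px = c(448L, 448L),
                          n_islets = 2L,
                          cells_per_islet = list(mean = 30, dispersion = 1e6),
                          cell_type_fractions = c(beta = 0.6, alpha = 0.4,
                                                  delta = 0),
                          marker_models = mm, morphology = morph,
                          coloc_fraction = c("GCG:PC13" = 0.6),
                          exocrine_fill = 0.2, noise_sd = 0,
                          background_level = 0,
                          illumination_gradient_amplitude = 0)
  fr <- unlist(lapply(1:2, function(sd_) {
    s <- render_islet_image(cfg, seed = sd_)
    islets <- detect_islets(s$image, c("GCG", "SST", "PC13"))
    img <- subtract_background(s$image, islets)
    vapply(islets, function(isl)
      measure_islet(isl, img, channels = c("GCG", "SST", "PC13"))$frac_GCG,
      numeric(1))
  }))
  expect_lt(abs(mean(fr) - 0.40), 0.05)
})

test_that("Manders coefficients: closed forms and symmetry", {
  a <- c(rep(2, 100))
  b <- c(rep(0, 50), rep(3, 50))
  expect_equal(unname(manders_coefficients(a, a, 1, 1)), c(1, 1))
  expect_equal(unname(manders_coefficients(c(1, 1, 0, 0), c(0, 0, 1, 1),
                                           0.5, 0.5)), c(0, 0))
  mm <- manders_coefficients(a, b, 1, 1)
  expect_equal(mm[["M1"]], 0.5)   # A uniform on 100 px, B covers 50 of them
  expect_equal(mm[["M2"]], 1.0)
  expect_warning(m0 <- manders_coefficients(c(0, 0), c(1, 1), 1, 1),
                 "M1 undefined")
  expect_true(is.na(m0[["M1"]]))
})

test_that("measured Manders rises monotonically with the coloc fraction", {
  levels <- c(0.2, 0.4, 0.6, 0.8, 1.0)
  m_mean <- vapply(levels, function(f) {
    cfg <- tiny_config(coloc_fraction = c("INS:PC13" = f))
    s <- render_islet_image(cfg, seed = 40)
    ires <- analyze_islets(s$image)
    islets <- attr(ires, "islets"); pimg <- attr(ires, "image")
    cells <- analyze_cells(pimg, islets, coloc_pair = c("INS", "PC13"),
                           thresholds = c(INS = 3000, ProINS = 3000,
                                          PC13 = 3000))
    mean(cells$cell_m1_INS_PC13, na.rm = TRUE)
  }, numeric(1))
  expect_gt(cor(m_mean, levels, method = "spearman"), 0.95)
})
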