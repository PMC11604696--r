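# Shared fixtures: small, fast generator configurations and constructed
# images. All randomness is seeded per test.

# compact single-islet world for fast rendering
tiny_config <- function(..., n_islets = 1L, noise_sd = 80,
                        background_level = 250, exocrine_fill = 0.3,
                        cells_per_islet = list(mean = 14, dispersion = 1e6)) {
  generator_config(image_shape_px = c(320L, 320L), n_islets = n_islets,
                   cells_per_islet = cells_per_islet,
                   exocrine_fill = exocrine_fill, noise_sd = noise_sd,
                   background_level = background_level, ...)
}

# noiseless, clean-field variant (no background, no gradient, no shift)
clean_config <- function(...) {
  tiny_config(noise_sd = 0, background_level = 0,
              illumination_gradient_amplitude = 0, ...)
}

# marker models with every endocrine cell positive for at least one marker
# (all tissue optically visible; used by detection-coverage tests)
visible_models_A <- function() {
  mm <- isletquant:::default_marker_models("A")
  mm$alpha$PC13$p_pos <- 0.95
  mm$delta$PC13$p_pos <- 0.95
  mm
}

# brute-force Otsu oracle: exhaustive search over all 256 cut levels of the
# quantised histogram, maximising between-class variance; returns the
# 0-based cut level
bf_otsu_level <- function(x, n_levels = 256L) {
  x <- as.numeric(x)
  lo <- min(x); hi <- max(x)
  q <- round((x - lo) / (hi - lo) * (n_levels - 1))
  best <- -Inf; best_k <- NA_integer_
  for (k in 0:(n_levels - 2L)) {
    g0 <- q <= k
    w0 <- mean(g0)
    if (w0 == 0 || w0 == 1) next
    sb <- w0 * (1 - w0) * (mean(q[g0]) - mean(q[!g0]))^2
    if (sb > best) { best <- sb; best_k <- k }
  }
  best_k
}

# paint a disk into a matrix
paint_disk <- function(m, cr, cc, r, value) {
  for (i in max(1, floor(cr - r)):min(nrow(m), ceiling(cr + r)))
    for (j in max(1, floor(cc - r)):min(ncol(m), ceiling(cc + r)))
      if ((i - cr)^2 + (j - cc)^2 <= r^2) m[i, j] <- value
  m
}
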