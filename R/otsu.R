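#' Otsu threshold of an intensity distribution
#'
#' Computes the global threshold maximising the between-class variance of the
#' intensity histogram, after quantising the observed range to `n_levels`
#' grey levels (`q = round((x - min) / (max - min) * (n_levels - 1))`). The
#' search is over cut levels `k`: class 0 is `q <= k`, class 1 is `q > k`.
#' The returned threshold is the intensity half-way between levels `k` and
#' `k + 1`, i.e. `min + (k + 0.5) * (max - min) / (n_levels - 1)`, so that
#' classifying pixels by `x >= threshold` reproduces the optimal split. For
#' integer 8-bit data this is exactly the classical 256-bin Otsu cut.
#'
#' @param x numeric vector or matrix of intensities.
#' @param n_levels number of quantisation levels (default 256).
#' @return the threshold intensity (scalar), with attribute `level` giving
#'   the cut level `k` on the quantised scale.
#' @export
otsu_threshold <- function(x, n_levels = 256L) {
  x <- as.numeric(x)
  x <- x[is.finite(x)]
  if (length(x) < 2) stop("need at least 2 intensities")
  lo <- min(x); hi <- max(x)
  if (hi <= lo) stop("degenerate histogram: all intensities identical")
  q <- round((x - lo) / (hi - lo) * (n_levels - 1))
  h <- tabulate(q + 1L, nbins = n_levels)
  p <- h / sum(h)
  levels <- seq_len(n_levels) - 1
  omega <- cumsum(p)                # P(class 0) for cut after each level
  mu <- cumsum(p * levels)          # partial first moment
  mu_t <- mu[n_levels]
  k_all <- seq_len(n_levels - 1L)   # cut after level k-1 (0-based k_all-1)
  w0 <- omega[k_all]
  valid <- w0 > 0 & w0 < 1
  sigma_b <- rep(-Inf, n_levels - 1L)
  sigma_b[valid] <- (mu_t * w0[valid] - mu[k_all][valid])^2 /
    (w0[valid] * (1 - w0[valid]))
  k <- which.max(sigma_b) - 1L      # 0-based cut level
  thr <- lo + (k + 0.5) * (hi - lo) / (n_levels - 1)
  attr(thr, "level") <- k
  # Otsu's effectiveness measure: between-class / total variance at the cut
  sigma_t <- sum(p * (levels - mu_t)^2)
  attr(thr, "eta") <- if (sigma_t > 0) max(sigma_b) / sigma_t else 0
  thr
}
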