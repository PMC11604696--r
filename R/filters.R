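# Separable Gaussian smoothing and blob detection built on the compiled
# grid primitives. Edge handling: truncated kernels renormalised so that a
# constant image is a fixed point of the filter.

gaussian_kernel <- function(sigma) {
  half <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-half, half))^2 / (2 * sigma^2))
  k / sum(k)
}

# n x n banded convolution operator with edge renormalisation
conv_operator <- function(n, kernel) {
  half <- (length(kernel) - 1L) / 2L
  A <- matrix(0, n, n)
  for (j in seq(-half, half)) {
    i <- seq_len(n)
    tgt <- i + j
    ok <- tgt >= 1 & tgt <= n
    A[cbind(i[ok], tgt[ok])] <- A[cbind(i[ok], tgt[ok])] + kernel[j + half + 1L]
  }
  A / rowSums(A)
}

#' Gaussian blur of an intensity plane
#'
#' Separable Gaussian filter; truncated edge kernels are renormalised so a
#' constant plane is unchanged.
#'
#' @param plane numeric matrix.
#' @param sigma_px standard deviation in pixels.
#' @return smoothed matrix of the same dimensions.
#' @export
gaussian_blur <- function(plane, sigma_px) {
  stopifnot(is.matrix(plane), sigma_px > 0)
  k <- gaussian_kernel(sigma_px)
  Ar <- conv_operator(nrow(plane), k)
  Ac <- conv_operator(ncol(plane), k)
  Ar %*% plane %*% t(Ac)
}

# Local maxima of a plane: pixels equal to the max in a disk of radius
# min_distance_px and above abs_threshold. Plateaus keep their first pixel
# (column-major order) within each connected plateau component.
local_maxima <- function(plane, min_distance_px, abs_threshold = -Inf) {
  mx <- .max_filter_disk(plane, min_distance_px)
  cand <- plane >= mx & plane >= abs_threshold
  if (!any(cand)) return(matrix(integer(0), 0, 2))
  lab <- .cc_label(matrix(as.integer(cand), nrow(plane)))
  n <- max(lab)
  first <- match(seq_len(n), lab[lab > 0])
  pos <- which(lab > 0)[first]
  cbind(row = (pos - 1L) %% nrow(plane) + 1L,
        col = (pos - 1L) %/% nrow(plane) + 1L)
}

# Connected-component areas (pixel counts) of a label matrix
label_areas <- function(labels) {
  if (max(labels) == 0L) return(integer(0))
  tabulate(labels[labels > 0L], nbins = max(labels))
}

# Centroids (row, col) of each label
label_centroids <- function(labels) {
  n <- max(labels)
  if (n == 0L) return(matrix(numeric(0), 0, 2))
  pos <- which(labels > 0L)
  l <- labels[pos]
  r <- (pos - 1L) %% nrow(labels) + 1L
  c <- (pos - 1L) %/% nrow(labels) + 1L
  cbind(row = rowsum(r, l)[, 1] / tabulate(l, n),
        col = rowsum(c, l)[, 1] / tabulate(l, n))
}
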