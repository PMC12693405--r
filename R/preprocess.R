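# Gaussian smoothing with ImageJ-radius semantics and histogram utilities
# shared by the threshold and ridge methods.

# Sampled Gaussian and Gaussian-derivative correlation kernels, normalized so
# that discrete responses are exact on low-order polynomials:
#   order 0: sum(w) = 1           (constants preserved)
#   order 1: sum(k * w) = 1       (ramp I = x -> response 1)
#   order 2: sum(k^2/2 * w) = 1, sum(w) = 0   (I = x^2/2 -> response 1)
gauss_kernel <- function(sigma, order = 0L, truncation = 4) {
  if (sigma <= 0) stop("sigma must be positive")
  r <- max(1L, as.integer(ceiling(truncation * sigma)))
  k <- (-r):r
  g <- dnorm(k, sd = sigma)
  if (order == 0L) {
    g / sum(g)
  } else if (order == 1L) {
    w <- k * g
    w / sum(k * w)
  } else if (order == 2L) {
    w <- (k^2 - sigma^2) * g
    w <- w - mean(w)
    w / sum(k^2 * w / 2)
  } else {
    stop("order must be 0, 1, or 2")
  }
}

# Correlate each column of `m` with kernel `w` (odd length), reflecting the
# signal at the boundary (edge value included in the mirror).
corr_cols <- function(m, w) {
  r <- (length(w) - 1L) %/% 2L
  n <- nrow(m)
  i <- seq(1L - r, n + r)           # reflect out-of-range indices (edge
  j <- (i - 1L) %% (2L * n)         # value included in the mirror)
  idx <- ifelse(j < n, j + 1L, 2L * n - j)
  p <- m[idx, , drop = FALSE]
  out <- matrix(0, n, ncol(m))
  for (k in seq_along(w)) {
    if (w[k] != 0) out <- out + w[k] * p[(k - 1L) + seq_len(n), , drop = FALSE]
  }
  out
}

# Separable correlation: kernel wx along x (columns), wy along y (rows).
corr_sep <- function(m, wx, wy) {
  t(corr_cols(t(corr_cols(m, wy)), wx))
}

#' Gaussian blur with ImageJ-radius semantics
#'
#' Separable Gaussian convolution where `radius` is the Gaussian sigma in
#' pixels (the parameterization of ImageJ's "Accurate Gaussian Blur").
#' Boundaries are handled by reflection, so constants are preserved and
#' interior mass is conserved.
#'
#' @param image a [calibrated_image()].
#' @param radius Gaussian sigma in pixels (> 0). The threshold method uses
#'   2.00 and the ridge method 4.00 by default.
#' @param truncation kernel support in multiples of sigma (default 4).
#' @return A blurred [calibrated_image()] with the same shape and scale.
#' @export
gaussian_blur <- function(image, radius, truncation = 4) {
  if (!is.numeric(radius) || radius <= 0) stop("blur radius must be positive")
  if (truncation < 3) stop("truncation must be at least 3 sigma")
  w <- gauss_kernel(radius, 0L, truncation)
  out <- corr_sep(image$pixels, w, w)
  calibrated_image(out, image$scale, bit_depth = image$bit_depth,
                   source_id = image$source_id)
}

#' Intensity histogram of a masked region
#'
#' Bins span the image's bit-depth range (8-bit sources: 256 unit bins over
#' 0..255; float images: `n_bins` bins over `[0, 1]`), so counts sum to the
#' number of masked pixels.
#'
#' @param image a [calibrated_image()].
#' @param mask logical matrix matching the image shape; must select at least
#'   one pixel.
#' @param n_bins number of bins (default 256).
#' @return A list with `counts`, `breaks` (length `n_bins + 1`) and `mids`.
#' @export
roi_histogram <- function(image, mask, n_bins = 256L) {
  if (!identical(dim(mask), dim(image$pixels))) {
    stop("mask shape must match the image")
  }
  if (!any(mask)) stop("mask selects no pixels")
  vals <- image$pixels[mask]
  if (identical(image$bit_depth, "float")) {
    top <- 1
  } else {
    top <- 2^as.numeric(image$bit_depth) - 1
  }
  breaks <- seq(0, top, length.out = n_bins + 1L)
  bin <- pmin(pmax(floor(vals / top * n_bins), 0), n_bins - 1L)
  counts <- tabulate(bin + 1L, nbins = n_bins)
  list(counts = counts, breaks = breaks,
       mids = (breaks[-1] + breaks[-length(breaks)]) / 2)
}
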