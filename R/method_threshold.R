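# Method 1: automatic Yen thresholding of the ROI and SD fractional area.

#' Yen's maximum-correlation threshold
#'
#' Selects the histogram bin that maximizes Yen's maximum-correlation
#' criterion (Yen, Chang & Chang 1995), evaluated at every candidate split;
#' ties are broken toward the lowest bin index. The returned index `t`
#' partitions the histogram into bins `0..t` (at or below threshold) and
#' `t+1..` (above).
#'
#' @param hist a histogram as returned by [roi_histogram()], or a plain
#'   vector of bin counts.
#' @return Zero-based bin index of the optimal threshold.
#' @export
yen_threshold <- function(hist) {
  counts <- if (is.list(hist)) hist$counts else hist
  counts <- as.numeric(counts)
  if (sum(counts > 0) < 2L) {
    stop("degenerate histogram: need at least two populated bins")
  }
  p <- counts / sum(counts)
  P1 <- cumsum(p)
  P1sq <- cumsum(p^2)
  P2sq <- sum(p^2) - P1sq
  term1 <- ifelse(P1sq * P2sq > 0, -log(P1sq * P2sq), 0)
  term2 <- ifelse(P1 * (1 - P1) > 0, 2 * log(P1 * (1 - P1)), 0)
  crit <- term1 + term2
  # only candidates that separate two nonempty classes are admissible
  nz <- which(counts > 0)
  valid <- seq(min(nz), max(nz) - 1L)
  valid[which.max(crit[valid])] - 1L
}

#' SD fraction by Yen thresholding (Method 1)
#'
#' Pipeline: Gaussian blur (default radius 2.00) of the whole image, ROI
#' intensity histogram, Yen threshold, then the SD binary is the set of ROI
#' pixels on the slit side of the threshold. Slit diaphragms are recessed
#' grooves and image dark in secondary-electron SEM, so the default polarity
#' takes intensities at or below the threshold.
#'
#' @param image a [calibrated_image()].
#' @param roi a [polygon_roi()] within the image.
#' @param blur_radius Gaussian sigma in pixels; default 2.00.
#' @param polarity `"dark"` (default; SD = intensity at or below threshold)
#'   or `"bright"`.
#' @param n_bins histogram bins (default 256, matching 8-bit practice).
#' @param truncation blur kernel support in sigmas.
#' @return An `sd_measurement` list: `sd_fraction` (percent of ROI area),
#'   `sd_area`, `roi_area` (pixels), `threshold_bin`, `threshold_level`,
#'   `method`, `parameters`, and an `sd_mask` matrix.
#' @export
sd_fraction_by_threshold <- function(image, roi, blur_radius = 2,
                                     polarity = c("dark", "bright"),
                                     n_bins = 256L, truncation = 4) {
  polarity <- match.arg(polarity)
  blurred <- gaussian_blur(image, blur_radius, truncation)
  mask <- rasterize_roi(roi, dim(image$pixels))
  hist <- roi_histogram(blurred, mask, n_bins)
  t_bin <- yen_threshold(hist)
  top <- if (identical(image$bit_depth, "float")) 1 else
    2^as.numeric(image$bit_depth) - 1
  bins <- pmin(pmax(floor(blurred$pixels / top * n_bins), 0), n_bins - 1L)
  sd_side <- if (polarity == "dark") bins <= t_bin else bins > t_bin
  sd_mask <- sd_side & mask
  new_sd_measurement(
    sd_fraction = 100 * sum(sd_mask) / sum(mask),
    sd_area = sum(sd_mask), roi_area = sum(mask),
    method = "threshold", sd_mask = sd_mask,
    threshold_bin = t_bin, threshold_level = hist$breaks[t_bin + 2L],
    parameters = list(blur_radius = blur_radius, polarity = polarity,
                      n_bins = n_bins),
    source_id = image$source_id, roi_label = roi$label
  )
}

new_sd_measurement <- function(...) {
  m <- list(...)
  stopifnot(m$sd_fraction >= 0, m$sd_fraction <= 100)
  structure(m, class = "sd_measurement")
}

#' @export
print.sd_measurement <- function(x, ...) {
  cat(sprintf("<sd_measurement> %s/%s [%s]: SD fraction %.2f%% (%d / %d px)\n",
              x$source_id, x$roi_label, x$method, x$sd_fraction,
              x$sd_area, x$roi_area))
  invisible(x)
}

#' Flatten a measurement to a one-row data.frame
#' @param x an `sd_measurement` or `profile_measurement`.
#' @return One-row data.frame suitable for [write_measurements()].
#' @export
measurement_row <- function(x) {
  if (inherits(x, "sd_measurement")) {
    data.frame(source_id = x$source_id, roi_label = x$roi_label,
               method = x$method, value = x$sd_fraction, units = "percent",
               sd_area = x$sd_area, roi_area = x$roi_area,
               parameters_hash = parameters_hash(x$parameters),
               stringsAsFactors = FALSE)
  } else if (inherits(x, "profile_measurement")) {
    data.frame(source_id = x$source_id, roi_label = x$roi_label,
               method = "profile", value = x$fpw, units = "um",
               sd_area = NA_integer_, roi_area = NA_integer_,
               parameters_hash = parameters_hash(x$parameters),
               stringsAsFactors = FALSE)
  } else {
    stop("unsupported measurement object")
  }
}

# Deterministic short hash of a parameter list (provenance bookkeeping).
parameters_hash <- function(params) {
  s <- paste(names(params), vapply(params, function(p)
    paste(format(p, digits = 12), collapse = ","), ""), sep = "=",
    collapse = ";")
  b <- as.integer(charToRaw(s))
  h <- 0
  for (x in b) h <- (h * 31 + x) %% 2147483647
  sprintf("%08x", h)
}
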