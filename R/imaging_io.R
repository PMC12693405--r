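#' Calibrated grayscale image
#'
#' A 2D grayscale intensity grid together with its physical pixel size.
#' The internal coordinate convention places pixel centers at integer
#' coordinates with the origin at the top-left pixel center, x increasing
#' rightward (matrix columns) and y increasing downward (matrix rows), so
#' matrix element `[r, c]` has center `(x = c - 1, y = r - 1)`.
#'
#' @param pixels numeric matrix of intensities (rows = y, columns = x).
#' @param scale physical pixel size in micrometers per pixel; must be > 0.
#' @param bit_depth source bit depth: 8, 16, or `"float"` for unit-range
#'   synthetic/derived images.
#' @param source_id identifier string carried through to measurements.
#' @return An object of class `calibrated_image`.
#' @export
calibrated_image <- function(pixels, scale, bit_depth = "float",
                             source_id = "image") {
  pixels <- as.matrix(pixels)
  if (!is.numeric(pixels)) stop("pixels must be numeric")
  if (!all(is.finite(pixels))) stop("intensities must be finite")
  if (nrow(pixels) < 1L || ncol(pixels) < 1L) stop("image must be non-empty")
  if (!is.numeric(scale) || length(scale) != 1L || !is.finite(scale) ||
      scale <= 0) {
    stop("scale (um/pixel) must be a single positive number")
  }
  structure(
    list(pixels = pixels, scale = scale, bit_depth = bit_depth,
         source_id = as.character(source_id)),
    class = "calibrated_image"
  )
}

#' @export
print.calibrated_image <- function(x, ...) {
  cat(sprintf("<calibrated_image> %s: %d x %d px, %.4g um/px, depth %s\n",
              x$source_id, ncol(x$pixels), nrow(x$pixels), x$scale,
              as.character(x$bit_depth)))
  invisible(x)
}

#' @export
dim.calibrated_image <- function(x) dim(x$pixels)

# Intensities rescaled to [0, 1] using the source bit depth.
img_norm01 <- function(image) {
  px <- image$pixels
  if (identical(image$bit_depth, "float")) {
    return(pmin(pmax(px, 0), 1))
  }
  px / (2^as.numeric(image$bit_depth) - 1)
}

#' Load a calibrated SEM image from a TIFF file
#'
#' Reads a single-channel 8- or 16-bit TIFF losslessly and attaches the
#' pixel-size calibration. Multi-channel inputs are collapsed to luminance
#' with a warning (Rec. 709 weights for 3 channels, channel mean otherwise).
#'
#' @param path path to a TIFF file.
#' @param scale micrometers per pixel (> 0).
#' @param source_id optional identifier; defaults to the file name.
#' @return A [calibrated_image()].
#' @export
load_image <- function(path, scale, source_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (!is.numeric(scale) || length(scale) != 1L || !is.finite(scale) ||
      scale <= 0) {
    stop("scale (um/pixel) must be a single positive number")
  }
  raw <- tiff::readTIFF(path, as.is = TRUE, info = TRUE)
  bps <- attr(raw, "bits.per.sample")
  bit_depth <- if (is.null(bps)) 8 else as.integer(bps)
  if (length(dim(raw)) == 3L) {
    nc <- dim(raw)[3]
    warning("multi-channel image collapsed to luminance (", nc, " channels)")
    w <- if (nc == 3L) c(0.2126, 0.7152, 0.0722) else rep(1 / nc, nc)
    px <- matrix(0, dim(raw)[1], dim(raw)[2])
    for (k in seq_len(nc)) px <- px + w[k] * raw[, , k]
  } else {
    px <- raw
  }
  storage.mode(px) <- "double"
  calibrated_image(px, scale, bit_depth = bit_depth,
                   source_id = source_id %||% basename(path))
}

#' Write a calibrated image to TIFF
#'
#' Integer-depth images are written losslessly at their stated bit depth;
#' float images are written as 16-bit after scaling the unit range.
#'
#' @param image a [calibrated_image()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  px <- image$pixels
  if (identical(image$bit_depth, "float")) {
    px <- round(pmin(pmax(px, 0), 1) * 65535)
    depth <- 16L
  } else {
    depth <- as.integer(image$bit_depth)
  }
  tiff::writeTIFF(px / (2^depth - 1), path, bits.per.sample = depth,
                  compression = "none")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Polygon region of interest
#'
#' @param vertices two-column matrix (x, y) of ordered vertex coordinates in
#'   the internal pixel-center convention; at least 3 vertices forming a
#'   simple (non-self-intersecting) polygon.
#' @param label ROI label.
#' @return An object of class `polygon_roi`.
#' @export
polygon_roi <- function(vertices, label = "roi") {
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 2L) stop("vertices must be an n x 2 matrix")
  if (nrow(vertices) < 3L) stop("a polygon needs at least 3 vertices")
  if (!all(is.finite(vertices))) stop("vertex coordinates must be finite")
  if (polygon_self_intersects(vertices)) {
    stop("polygon must be simple (non-self-intersecting)")
  }
  colnames(vertices) <- c("x", "y")
  structure(list(vertices = vertices, label = as.character(label)),
            class = "polygon_roi")
}

#' Polyline annotation (profile path)
#'
#' @param vertices two-column matrix (x, y), at least two distinct points.
#' @param label line label.
#' @return An object of class `polyline_roi`.
#' @export
polyline_roi <- function(vertices, label = "line") {
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 2L) stop("vertices must be an n x 2 matrix")
  if (nrow(vertices) < 2L) stop("a polyline needs at least 2 vertices")
  if (!all(is.finite(vertices))) stop("vertex coordinates must be finite")
  seg <- diff(vertices)
  if (sum(sqrt(rowSums(seg^2))) <= 0) stop("polyline must have positive length")
  colnames(vertices) <- c("x", "y")
  structure(list(vertices = vertices, label = as.character(label)),
            class = "polyline_roi")
}

# Segment-intersection test over non-adjacent edge pairs (small n).
polygon_self_intersects <- function(v) {
  n <- nrow(v)
  seg <- cbind(v, v[c(2:n, 1), , drop = FALSE])
  cross <- function(ox, oy, ax, ay, bx, by) (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  for (i in seq_len(n - 2L)) {
    for (j in seq(i + 2L, n)) {
      if (j > n || (i == 1L && j == n)) next  # adjacent via wraparound
      a <- seg[i, ]; b <- seg[j, ]
      d1 <- cross(a[1], a[2], a[3], a[4], b[1], b[2])
      d2 <- cross(a[1], a[2], a[3], a[4], b[3], b[4])
      d3 <- cross(b[1], b[2], b[3], b[4], a[1], a[2])
      d4 <- cross(b[1], b[2], b[3], b[4], a[3], a[4])
      if (((d1 > 0) != (d2 > 0)) && ((d3 > 0) != (d4 > 0))) return(TRUE)
    }
  }
  FALSE
}

#' Polygon area by the shoelace formula
#'
#' @param roi a [polygon_roi()].
#' @return Area in square pixels.
#' @export
polygon_area <- function(roi) {
  v <- roi$vertices
  n <- nrow(v)
  j <- c(2:n, 1)
  abs(sum(v[, 1] * v[j, 2] - v[j, 1] * v[, 2])) / 2
}

#' Rasterize a polygon ROI to a binary mask
#'
#' A pixel belongs to the mask exactly when its center lies inside the
#' polygon under the even-odd (ray-crossing) rule, using half-open edge
#' intervals so results are deterministic when centers fall on boundaries.
#'
#' @param roi a [polygon_roi()].
#' @param shape integer vector `c(height, width)` of the target image.
#' @return Logical matrix of dimension `shape`.
#' @export
rasterize_roi <- function(roi, shape) {
  h <- as.integer(shape[1]); w <- as.integer(shape[2])
  v <- roi$vertices
  n <- nrow(v)
  xc <- 0:(w - 1L)
  yc <- 0:(h - 1L)
  crossings <- matrix(0L, h, w)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    x1 <- v[i, 1]; y1 <- v[i, 2]; x2 <- v[j, 1]; y2 <- v[j, 2]
    if (y1 == y2) next
    rows <- which((y1 <= yc) != (y2 <= yc))
    if (!length(rows)) next
    xint <- x1 + (yc[rows] - y1) * (x2 - x1) / (y2 - y1)
    crossings[rows, ] <- crossings[rows, ] +
      outer(xint, xc, function(a, b) as.integer(b < a))
  }
  mask <- (crossings %% 2L) == 1L
  if (!any(mask)) stop("polygon covers no pixel centers inside the image")
  mask
}

#' Read ROI annotations
#'
#' Supports ImageJ `.roi` records, ImageJ `RoiSet.zip` archives, and a
#' plain-text polygon dialect (one ROI per line:
#' `"[polygon|polyline] [label] x,y x,y ..."`). ImageJ's pixel-corner
#' coordinates are shifted by -0.5 on read into the internal pixel-center
#' convention.
#'
#' @param path annotation file.
#' @param dialect `"imagej-roi"`, `"imagej-zip"`, or `"text-polygon"`;
#'   guessed from the file extension by default.
#' @return A list of [polygon_roi()] / [polyline_roi()] objects.
#' @export
read_rois <- function(path, dialect = c("auto", "imagej-roi", "imagej-zip",
                                        "text-polygon")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "auto") {
    ext <- tolower(tools::file_ext(path))
    dialect <- switch(ext,
      roi = "imagej-roi", zip = "imagej-zip", txt = "text-polygon",
      stop("cannot guess ROI dialect from extension '", ext, "'"))
  }
  switch(dialect,
    "imagej-roi" = list(read_imagej_roi(path)),
    "imagej-zip" = {
      exdir <- tempfile("roiset")
      files <- utils::unzip(path, exdir = exdir)
      on.exit(unlink(exdir, recursive = TRUE), add = TRUE)
      lapply(sort(files), read_imagej_roi)
    },
    "text-polygon" = read_text_rois(path)
  )
}
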