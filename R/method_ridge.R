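# Method 2: Steger curvilinear detection of slit grooves and SD area
# fraction. The detector follows the classic scheme: Gaussian-derivative
# responses, Hessian eigen-analysis with subpixel localization along the
# principal normal, hysteresis linking into lines, and width estimation from
# gradient-magnitude extrema along the line normal.

#' Ridge-detection parameters
#'
#' Defaults are the published parameter profile used for real micrographs:
#' sigma (scale) 5.70, line width 15 px, lower threshold 0.00, upper
#' threshold 0.17, minimum line length 5.00 px, maximum line length 0.00
#' (0 meaning unbounded). Saliency thresholds apply to scale-normalized
#' second-derivative magnitudes (`sigma^2 * |second directional derivative|`)
#' of intensities normalized to `[0, 1]`, so they are independent of source
#' bit depth.
#'
#' @param sigma detection scale in pixels (> 0).
#' @param line_width maximum line width in pixels (width search cap).
#' @param lower,upper hysteresis saliency thresholds, `0 <= lower <= upper`.
#' @param min_len minimum retained line length in pixels.
#' @param max_len maximum line length; 0 = unbounded.
#' @return A list of class `ridge_params`.
#' @export
ridge_params <- function(sigma = 5.7, line_width = 15, lower = 0,
                         upper = 0.17, min_len = 5, max_len = 0) {
  if (sigma <= 0) stop("sigma must be positive")
  if (line_width <= 0) stop("line_width must be positive")
  if (lower < 0 || upper < lower) stop("need 0 <= lower <= upper")
  if (min_len < 0) stop("min_len must be nonnegative")
  if (max_len < 0) stop("max_len must be nonnegative (0 = unbounded)")
  structure(list(sigma = sigma, line_width = line_width, lower = lower,
                 upper = upper, min_len = min_len, max_len = max_len),
            class = "ridge_params")
}

#' Gaussian-derivative responses
#'
#' Convolves an image with Gaussian-derivative kernels at scale `sigma`
#' (reflection boundary), returning the five responses needed by the line
#' detector. Kernels are normalized so a linear ramp has unit first
#' derivative and `x^2/2` unit second derivative.
#'
#' @param image a [calibrated_image()] or plain numeric matrix.
#' @param sigma derivative scale in pixels.
#' @param truncation kernel support in sigmas (default 4).
#' @return List with matrices `rx`, `ry`, `rxx`, `rxy`, `ryy` and `sigma`.
#' @export
gaussian_derivatives <- function(image, sigma, truncation = 4) {
  m <- if (inherits(image, "calibrated_image")) image$pixels else image
  g0 <- gauss_kernel(sigma, 0L, truncation)
  g1 <- gauss_kernel(sigma, 1L, truncation)
  g2 <- gauss_kernel(sigma, 2L, truncation)
  list(rx = corr_sep(m, g1, g0),
       ry = corr_sep(m, g0, g1),
       rxx = corr_sep(m, g2, g0),
       rxy = corr_sep(m, g1, g1),
       ryy = corr_sep(m, g0, g2),
       sigma = sigma)
}

#' Detect subpixel line points
#'
#' For every pixel the Hessian's principal eigen-direction (the line normal)
#' is computed; a pixel is a line point when the subpixel extremum of the
#' second-order Taylor expansion along that direction falls within the pixel
#' (`|t| <= 0.5`) and the signed principal second derivative matches the
#' requested polarity (dark lines: positive curvature). Saliency is the
#' scale-normalized principal second-derivative magnitude.
#'
#' @param derivs responses from [gaussian_derivatives()].
#' @param params a [ridge_params()]; points below `lower` are dropped.
#' @param polarity `"dark"` (default) or `"bright"` lines.
#' @return data.frame with columns `row`, `col` (1-based pixel), `x`, `y`
#'   (subpixel position), `nx`, `ny` (unit normal), `saliency`, `t`.
#' @export
detect_line_points <- function(derivs, params = ridge_params(),
                               polarity = c("dark", "bright")) {
  polarity <- match.arg(polarity)
  rxx <- derivs$rxx; rxy <- derivs$rxy; ryy <- derivs$ryy
  rx <- derivs$rx; ry <- derivs$ry
  h <- nrow(rxx); w <- ncol(rxx)
  # principal eigenvalue (largest magnitude) and eigenvector of the Hessian
  half_tr <- (rxx + ryy) / 2
  disc <- sqrt(((rxx - ryy) / 2)^2 + rxy^2)
  lam <- ifelse(half_tr >= 0, half_tr + disc, half_tr - disc)
  # eigenvector for lam: (rxy, lam - rxx), falling back to the axis for
  # diagonal Hessians
  nx <- rxy
  ny <- lam - rxx
  nrm <- sqrt(nx^2 + ny^2)
  axis_x <- abs(rxx - lam) <= abs(ryy - lam)
  bad <- nrm < .Machine$double.eps^0.5
  nx[bad] <- ifelse(axis_x[bad], 1, 0)
  ny[bad] <- ifelse(axis_x[bad], 0, 1)
  nrm[bad] <- 1
  nx <- nx / nrm; ny <- ny / nrm
  signed <- if (polarity == "dark") lam else -lam
  sal <- derivs$sigma^2 * signed
  denom <- lam
  denom[abs(denom) < .Machine$double.eps] <- NA
  t_off <- -(rx * nx + ry * ny) / denom
  keep <- !is.na(t_off) & abs(t_off) <= 0.5 & signed > 0 & sal >= params$lower
  idx <- which(keep)
  if (!length(idx)) {
    return(data.frame(row = integer(), col = integer(), x = numeric(),
                      y = numeric(), nx = numeric(), ny = numeric(),
                      saliency = numeric(), t = numeric()))
  }
  rr <- ((idx - 1L) %% h) + 1L
  cc <- ((idx - 1L) %/% h) + 1L
  data.frame(row = rr, col = cc,
             x = (cc - 1) + t_off[idx] * nx[idx],
             y = (rr - 1) + t_off[idx] * ny[idx],
             nx = nx[idx], ny = ny[idx],
             saliency = sal[idx], t = t_off[idx])
}

#' Link line points into ridge lines
#'
#' Hysteresis linking: lines are seeded at unused points with saliency at or
#' above `upper` (seeds visited in row-major order for determinism) and
#' extended through 8-neighborhood points with saliency at or above `lower`,
#' choosing at each step the neighbor with the smallest orientation
#' discontinuity, ties broken by subpixel distance. Lines shorter than
#' `min_len` are discarded; `max_len = 0` means unbounded.
#'
#' @param points data.frame from [detect_line_points()].
#' @param params a [ridge_params()].
#' @return List of `ridge_line` objects (`points` data.frame plus `length`).
#' @export
link_ridges <- function(points, params = ridge_params()) {
  if (nrow(points) == 0L) return(list())
  h <- max(points$row); w <- max(points$col)
  grid <- matrix(0L, h, w)
  grid[cbind(points$row, points$col)] <- seq_len(nrow(points))
  used <- logical(nrow(points))
  seeds <- which(points$saliency >= params$upper)
  seeds <- seeds[order(points$row[seeds], points$col[seeds])]
  nb <- cbind(dr = c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L),
              dc = c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L))

  next_point <- function(i, dirx, diry) {
    r <- points$row[i]; c <- points$col[i]
    best <- 0L; best_ang <- Inf; best_d <- Inf
    for (k in 1:8) {
      rr <- r + nb[k, 1L]; cc <- c + nb[k, 2L]
      if (rr < 1L || rr > h || cc < 1L || cc > w) next
      j <- grid[rr, cc]
      if (j == 0L || used[j]) next
      dx <- points$x[j] - points$x[i]; dy <- points$y[j] - points$y[i]
      if (dx * dirx + dy * diry <= 0) next  # only forward continuation
      # orientation discontinuity between tangents (mod pi)
      tx <- -points$ny[j]; ty <- points$nx[j]
      dot <- abs(tx * dirx + ty * diry)
      ang <- acos(pmin(1, dot))
      d <- sqrt(dx^2 + dy^2)
      if (ang < best_ang - 1e-12 ||
          (ang < best_ang + 1e-12 && d < best_d)) {
        best <- j; best_ang <- ang; best_d <- d
      }
    }
    best
  }

  extend <- function(i0, dirx, diry, budget) {
    out <- integer(0)
    len <- 0
    i <- i0
    repeat {
      j <- next_point(i, dirx, diry)
      if (j == 0L) break
      step <- sqrt((points$x[j] - points$x[i])^2 +
                   (points$y[j] - points$y[i])^2)
      if (budget > 0 && len + step > budget) break
      used[j] <<- TRUE
      out <- c(out, j)
      len <- len + step
      dirx <- points$x[j] - points$x[i]; diry <- points$y[j] - points$y[i]
      nn <- sqrt(dirx^2 + diry^2); dirx <- dirx / nn; diry <- diry / nn
      i <- j
    }
    out
  }

  lines <- list()
  for (s in seeds) {
    if (used[s]) next
    used[s] <- TRUE
    dirx <- -points$ny[s]; diry <- points$nx[s]
    budget <- if (params$max_len > 0) params$max_len / 2 else 0
    fwd <- extend(s, dirx, diry, budget)
    bwd <- extend(s, -dirx, -diry, budget)
    ord <- c(rev(bwd), s, fwd)
    pts <- points[ord, , drop = FALSE]
    len <- polyline_length(pts$x, pts$y)
    if (len < params$min_len) next
    lines[[length(lines) + 1L]] <-
      structure(list(points = pts, length = len), class = "ridge_line")
  }
  lines
}

polyline_length <- function(x, y) {
  if (length(x) < 2L) return(0)
  sum(sqrt(diff(x)^2 + diff(y)^2))
}

# Bilinear interpolation of matrix m at internal coordinates (x, y)
# (x = col - 1, y = row - 1); out-of-range samples clamp to the border.
interp2 <- function(m, x, y) {
  h <- nrow(m); w <- ncol(m)
  x <- pmin(pmax(x, 0), w - 1)
  y <- pmin(pmax(y, 0), h - 1)
  x0 <- pmin(floor(x), w - 2); y0 <- pmin(floor(y), h - 2)
  x0 <- pmax(x0, 0); y0 <- pmax(y0, 0)
  fx <- x - x0; fy <- y - y0
  i00 <- cbind(y0 + 1, x0 + 1); i01 <- cbind(y0 + 1, x0 + 2)
  i10 <- cbind(y0 + 2, x0 + 1); i11 <- cbind(y0 + 2, x0 + 2)
  m[i00] * (1 - fx) * (1 - fy) + m[i01] * fx * (1 - fy) +
    m[i10] * (1 - fx) * fy + m[i11] * fx * fy
}

#' Estimate per-point line widths
#'
#' For each line point the left and right edges are located at the
#' gradient-magnitude maxima along the line normal within `line_width / 2`;
#' sides without an interior maximum fall back to the cap.
#'
#' @param line a `ridge_line` from [link_ridges()].
#' @param derivs responses from [gaussian_derivatives()] (gradients are
#'   reused for edge localization).
#' @param params a [ridge_params()].
#' @param step sampling step along the normal, pixels.
#' @return The line with `width_left`, `width_right` columns added to its
#'   points and a `mean_width` field.
#' @export
estimate_widths <- function(line, derivs, params = ridge_params(),
                            step = 0.25) {
  pts <- line$points
  if (nrow(pts) == 0L) stop("empty line")
  gm2 <- derivs$rx^2 + derivs$ry^2
  cap <- params$line_width / 2
  s <- seq(step, cap, by = step)
  side_width <- function(sgn) {
    # samples: n_points x n_steps
    sx <- outer(pts$x, s * sgn, function(a, b) a) +
      outer(pts$nx, s, function(n, d) n * d) * sgn
    sy <- outer(pts$y, s * sgn, function(a, b) a) +
      outer(pts$ny, s, function(n, d) n * d) * sgn
    g <- matrix(interp2(gm2, as.vector(sx), as.vector(sy)), nrow(pts))
    k <- max.col(g, ties.method = "first")
    wd <- s[k]
    wd[k == length(s)] <- cap  # maximum at the window end: edge not found
    wd
  }
  pts$width_left <- side_width(-1)
  pts$width_right <- side_width(1)
  line$points <- pts
  line$mean_width <- mean(pts$width_left + pts$width_right)
  line
}

#' Build the SD binary mask from detected ridge lines
#'
#' Two constructions are provided. `"line-envelope"` (default) treats the
#' detected dark lines as the slits themselves and fills the per-point width
#' envelope around each centerline. `"inter-ridge"` treats detected lines as
#' the ridges flanking the slits and fills ROI pixels lying between paired
#' adjacent centerlines whose mutual distance along the normal is at most
#' `line_width`. Both return a mask restricted to the ROI.
#'
#' @param lines list of `ridge_line` objects (with widths for envelope mode).
#' @param roi_mask logical ROI mask.
#' @param mode `"line-envelope"` or `"inter-ridge"`.
#' @param params a [ridge_params()].
#' @return Logical mask of the same shape as `roi_mask`.
#' @export
sd_mask_from_ridges <- function(lines, roi_mask,
                                mode = c("line-envelope", "inter-ridge"),
                                params = ridge_params()) {
  mode <- match.arg(mode)
  if (!any(roi_mask)) stop("empty ROI")
  h <- nrow(roi_mask); w <- ncol(roi_mask)
  mask <- matrix(FALSE, h, w)
  if (!length(lines)) return(mask)
  mark <- function(xs, ys) {
    rr <- round(ys) + 1L; cc <- round(xs) + 1L
    ok <- rr >= 1L & rr <= h & cc >= 1L & cc <= w
    mask[cbind(rr[ok], cc[ok])] <<- TRUE
  }
  if (mode == "line-envelope") {
    for (ln in lines) {
      pts <- resample_line(ln, ds = 0.5)
      for (i in seq_len(nrow(pts))) {
        tt <- seq(-pts$width_left[i], pts$width_right[i], by = 0.25)
        xs <- pts$x[i] + tt * pts$nx[i]
        ys <- pts$y[i] + tt * pts$ny[i]
        # keep the pixel-center-inside convention: a pixel belongs to the
        # envelope only if its center's offset along the normal is in range
        cx <- round(xs); cy <- round(ys)
        t_c <- (cx - pts$x[i]) * pts$nx[i] + (cy - pts$y[i]) * pts$ny[i]
        ok <- t_c >= -pts$width_left[i] & t_c <= pts$width_right[i]
        mark(xs[ok], ys[ok])
      }
    }
  } else {
    centers <- matrix(0L, h, w)
    for (li in seq_along(lines)) {
      pts <- resample_line(lines[[li]], ds = 0.5)
      rr <- round(pts$y) + 1L; cc <- round(pts$x) + 1L
      ok <- rr >= 1L & rr <= h & cc >= 1L & cc <= w
      centers[cbind(rr[ok], cc[ok])] <- li
    }
    for (li in seq_along(lines)) {
      pts <- resample_line(lines[[li]], ds = 0.5)
      for (i in seq_len(nrow(pts))) {
        for (sgn in c(-1, 1)) {
          tt <- seq(0.5, params$line_width, by = 0.5)
          xs <- pts$x[i] + sgn * tt * pts$nx[i]
          ys <- pts$y[i] + sgn * tt * pts$ny[i]
          rr <- round(ys) + 1L; cc <- round(xs) + 1L
          ok <- which(rr >= 1L & rr <= h & cc >= 1L & cc <= w)
          if (!length(ok)) next
          ids <- centers[cbind(rr[ok], cc[ok])]
          hit <- which(ids != 0L & ids != li)[1]
          if (!is.na(hit)) {
            sel <- ok[seq_len(hit)]
            mask[cbind(rr[sel], cc[sel])] <- TRUE
          }
        }
      }
    }
  }
  mask & roi_mask
}

# Resample a ridge line at uniform arc-length spacing, interpolating
# positions, normals, and (when present) widths.
resample_line <- function(line, ds = 0.5) {
  pts <- line$points
  if (nrow(pts) == 1L) {
    if (is.null(pts$width_left)) { pts$width_left <- 0; pts$width_right <- 0 }
    return(pts)
  }
  seg <- sqrt(diff(pts$x)^2 + diff(pts$y)^2)
  s <- c(0, cumsum(seg))
  si <- seq(0, s[length(s)], by = ds)
  fint <- function(v) approx(s, v, xout = si, rule = 2)$y
  out <- data.frame(x = fint(pts$x), y = fint(pts$y))
  # normals interpolated component-wise then renormalized (sign-aligned
  # first so antiparallel neighbors do not cancel)
  nx <- pts$nx; ny <- pts$ny
  for (i in seq_len(nrow(pts) - 1L)) {
    if (nx[i] * nx[i + 1L] + ny[i] * ny[i + 1L] < 0) {
      nx[i + 1L] <- -nx[i + 1L]; ny[i + 1L] <- -ny[i + 1L]
    }
  }
  onx <- fint(nx); ony <- fint(ny)
  nn <- pmax(sqrt(onx^2 + ony^2), 1e-9)
  out$nx <- onx / nn; out$ny <- ony / nn
  out$width_left <- if (is.null(pts$width_left)) 0 else fint(pts$width_left)
  out$width_right <- if (is.null(pts$width_right)) 0 else fint(pts$width_right)
  out
}

#' SD fraction by ridge detection (Method 2)
#'
#' Full pipeline: intensity normalization to `[0, 1]`, Gaussian blur
#' (default radius 4.00), Gaussian-derivative responses at `params$sigma`,
#' subpixel line-point detection, hysteresis linking, width estimation, SD
#' mask construction, and the area fraction
#' `100 * |mask| / |ROI|`.
#'
#' @inheritParams sd_fraction_by_threshold
#' @param params a [ridge_params()].
#' @param mode SD mask construction, see [sd_mask_from_ridges()].
#' @param blur_radius pre-smoothing sigma in pixels; default 4.00.
#' @return An `sd_measurement` (method `"ridge"`) with the SD mask and the
#'   detected lines attached.
#' @export
sd_fraction_by_ridge <- function(image, roi, blur_radius = 4,
                                 params = ridge_params(),
                                 mode = c("line-envelope", "inter-ridge"),
                                 polarity = c("dark", "bright")) {
  mode <- match.arg(mode)
  polarity <- match.arg(polarity)
  norm <- calibrated_image(img_norm01(image), image$scale, "float",
                           image$source_id)
  blurred <- gaussian_blur(norm, blur_radius)
  roi_mask <- rasterize_roi(roi, dim(image$pixels))
  derivs <- gaussian_derivatives(blurred, params$sigma)
  pts <- detect_line_points(derivs, params, polarity)
  lines <- link_ridges(pts, params)
  lines <- lapply(lines, estimate_widths, derivs = derivs, params = params)
  mask <- sd_mask_from_ridges(lines, roi_mask, mode, params)
  new_sd_measurement(
    sd_fraction = 100 * sum(mask) / sum(roi_mask),
    sd_area = sum(mask), roi_area = sum(roi_mask),
    method = "ridge", sd_mask = mask, lines = lines,
    parameters = c(list(blur_radius = blur_radius, mode = mode,
                        polarity = polarity), unclass(params)),
    source_id = image$source_id, roi_label = roi$label
  )
}

#' Parameter sweep against ground truth
#'
#' Evaluates a grid of ridge-detection parameter sets against images with
#' known slit masks, reporting detection sensitivity (fraction of true slit
#' pixels covered by the SD mask), false-positive area fraction (SD mask
#' outside the true slits), and the Youden-style score
#' `J = sensitivity - false-positive rate` used for ranking. This mirrors
#' the practice of tuning detector parameters on a ground-truthed training
#' set before fixing them for a study.
#'
#' @param truth_set list of items, each a list with elements `image`
#'   ([calibrated_image()]), `roi` ([polygon_roi()]), and `slit_mask`
#'   (logical ground-truth matrix).
#' @param grid data.frame whose columns are any of the [ridge_params()]
#'   fields plus optionally `blur_radius` and `mode`; missing columns take
#'   defaults.
#' @param blur_radius default pre-smoothing sigma for rows without one.
#' @param mode default mask construction mode.
#' @return The grid with `sensitivity`, `fp_rate`, `J`, and `degenerate`
#'   columns, ordered by decreasing `J` (degenerate rows last).
#' @export
sweep_parameters <- function(truth_set, grid, blur_radius = 4,
                             mode = "line-envelope") {
  if (!length(truth_set)) stop("need at least one ground-truthed image")
  if (!is.data.frame(grid) || nrow(grid) == 0L) stop("empty parameter grid")
  res <- grid
  res$sensitivity <- NA_real_; res$fp_rate <- NA_real_
  res$J <- NA_real_; res$degenerate <- FALSE
  defaults <- unclass(ridge_params())
  for (i in seq_len(nrow(grid))) {
    p <- defaults
    for (nm in intersect(names(grid), names(defaults))) p[[nm]] <- grid[[nm]][i]
    pars <- do.call(ridge_params, p)
    br <- if ("blur_radius" %in% names(grid)) grid$blur_radius[i] else blur_radius
    md <- if ("mode" %in% names(grid)) as.character(grid$mode[i]) else mode
    sens <- fpr <- numeric(0)
    for (item in truth_set) {
      roi_mask <- rasterize_roi(item$roi, dim(item$image$pixels))
      meas <- sd_fraction_by_ridge(item$image, item$roi, blur_radius = br,
                                   params = pars, mode = md)
      truth <- item$slit_mask & roi_mask
      neg <- roi_mask & !truth
      sens <- c(sens, if (sum(truth)) sum(meas$sd_mask & truth) / sum(truth)
                      else NA_real_)
      fpr <- c(fpr, if (sum(neg)) sum(meas$sd_mask & neg) / sum(neg)
                    else NA_real_)
    }
    if (all(is.na(sens))) {
      res$degenerate[i] <- TRUE
      res$fp_rate[i] <- mean(fpr, na.rm = TRUE)
    } else {
      res$sensitivity[i] <- mean(sens, na.rm = TRUE)
      res$fp_rate[i] <- mean(fpr, na.rm = TRUE)
      res$J[i] <- res$sensitivity[i] - res$fp_rate[i]
    }
  }
  res[order(res$degenerate, -ifelse(is.na(res$J), -Inf, res$J)), ,
      drop = FALSE]
}
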