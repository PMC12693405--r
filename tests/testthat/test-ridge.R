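# Synthetic curvilinear structures with known geometry for detector tests.

gaussian_line_image <- function(n = 60, angle = 0, offset = 0, amp = 0.5,
                                s = 3, bg = 0.9) {
  x <- matrix(rep(0:(n - 1), each = n), n, n)
  y <- matrix(rep(0:(n - 1), times = n), n, n)
  th <- angle * pi / 180
  cx <- (n - 1) / 2; cy <- (n - 1) / 2
  dist <- cos(th) * (x - cx) + sin(th) * (y - cy) - offset
  calibrated_image(bg - amp * exp(-dist^2 / (2 * s^2)), 0.01)
}

test_that("Gaussian-derivative responses match closed forms", {
  const <- calibrated_image(matrix(0.4, 40, 40), 0.01)
  d <- gaussian_derivatives(const, 3)
  for (nm in c("rx", "ry", "rxx", "rxy", "ryy")) {
    expect_lt(max(abs(d[[nm]])), 1e-12)
  }

  ramp <- calibrated_image(matrix(rep(0:59, each = 40), 40, 60), 0.01)
  d <- gaussian_derivatives(ramp, 2.5)
  interior <- function(m) m[11:30, 16:45]
  expect_equal(interior(d$rx), matrix(1, 20, 30), tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_lt(max(abs(interior(d$ry))), 1e-6)
  expect_lt(max(abs(interior(d$rxx))), 1e-6)

  # Gaussian-profile bar: second derivative across the bar center has the
  # closed form -amp * s / (s^2 + sigma^2)^(3/2)
  img <- gaussian_line_image(n = 81, amp = -1, s = 4, bg = 0)  # bright bar
  sg <- 2.5
  d <- gaussian_derivatives(img, sg)
  analytic <- -1 * 4 / (4^2 + sg^2)^1.5
  expect_lt(abs(d$rxx[41, 41] - analytic), 1e-4)
})

test_that("line points localize a dark line to subpixel accuracy", {
  d <- gaussian_derivatives(calibrated_image(matrix(0.5, 30, 30), 0.01), 3)
  expect_equal(nrow(detect_line_points(d, ridge_params(sigma = 3))), 0)

  # vertical dark line at a subpixel x position
  img <- gaussian_line_image(n = 60, angle = 0, offset = 0.3, s = 3)
  d <- gaussian_derivatives(img, 3)
  pts <- detect_line_points(d, ridge_params(sigma = 3, upper = 0.05))
  pts <- pts[pts$row > 8 & pts$row < 53, ]
  expect_gt(nrow(pts), 30)
  true_x <- (60 - 1) / 2 + 0.3
  expect_lt(max(abs(pts$x - true_x)), 0.1)
  expect_true(all(pts$saliency > 0))
  expect_true(all(abs(pts$t) <= 0.5))

  # same construction rotated 30 degrees: perpendicular residual <= 0.15 px
  img30 <- gaussian_line_image(n = 60, angle = 30, offset = 0.3, s = 3)
  d30 <- gaussian_derivatives(img30, 3)
  p30 <- detect_line_points(d30, ridge_params(sigma = 3, upper = 0.05))
  cx <- (60 - 1) / 2
  resid <- cos(pi / 6) * (p30$x - cx) + sin(pi / 6) * (p30$y - cx) - 0.3
  keep <- p30$row > 10 & p30$row < 51 & p30$col > 10 & p30$col < 51
  expect_gt(sum(keep), 20)
  expect_lt(max(abs(resid[keep])), 0.15)
})

test_that("hysteresis linking follows seeds, bridges, and length filters", {
  mk_pts <- function(xs, sal) {
    data.frame(row = 11L, col = as.integer(xs + 1), x = xs, y = 10,
               nx = 0, ny = 1, saliency = sal, t = 0)
  }
  # low-saliency bridge between two strong collinear segments -> one line
  pts <- mk_pts(0:10, c(rep(1, 5), 0.2, rep(1, 5)))
  lines <- link_ridges(pts, ridge_params(sigma = 1, lower = 0.1, upper = 0.5,
                                         min_len = 5))
  expect_length(lines, 1)
  expect_equal(nrow(lines[[1]]$points), 11)
  expect_equal(lines[[1]]$length, 10)

  # 3-point line is shorter than min_len = 5 -> discarded
  short <- mk_pts(0:2, rep(1, 3))
  expect_length(link_ridges(short, ridge_params(sigma = 1, min_len = 5)), 0)

  # nothing reaches the seeding threshold -> no lines at all
  weak <- mk_pts(0:10, rep(0.3, 11))
  expect_length(link_ridges(weak, ridge_params(sigma = 1, lower = 0.1,
                                               upper = 0.5, min_len = 2)), 0)
})

test_that("raising the seeding threshold never increases retained lines", {
  pat <- cohort_scale_pattern(30, size = 250L)
  norm <- gaussian_blur(pat$image, 4)
  d <- gaussian_derivatives(norm, 5)
  pts <- detect_line_points(d, ridge_params(sigma = 5, lower = 0))
  n_prev <- Inf
  for (up in c(0.05, 0.17, 0.3, 0.6)) {
    n <- length(link_ridges(pts, ridge_params(sigma = 5, lower = 0,
                                              upper = up, min_len = 5)))
    expect_lte(n, n_prev)
    n_prev <- n
  }
})

test_that("width estimation finds bar edges and respects the cap", {
  # trapezoid bar of full width 8 (plateau +- 4, sharp shoulders)
  n <- 81
  x <- matrix(rep(0:(n - 1), each = n), n, n)
  dist <- x - (n - 1) / 2
  prof <- (pnorm((dist + 4) / 1) - pnorm((dist - 4) / 1))
  img <- calibrated_image(0.9 - 0.5 * prof, 0.01)
  par8 <- ridge_params(sigma = 2.31, line_width = 15, upper = 0.05)
  d <- gaussian_derivatives(img, 2.31)
  lines <- link_ridges(detect_line_points(d, par8), par8)
  expect_gte(length(lines), 1)
  wl <- estimate_widths(lines[[1]], d, par8)
  expect_equal(wl$mean_width, 8, tolerance = 1.5)

  # very wide Gaussian bar: no gradient maximum inside the window -> cap
  wide <- gaussian_line_image(n = 81, s = 20, amp = 0.5)
  parw <- ridge_params(sigma = 2.31, line_width = 15, upper = 1e-4)
  dw <- gaussian_derivatives(wide, 2.31)
  lw <- link_ridges(detect_line_points(dw, parw), parw)
  expect_gte(length(lw), 1)
  ww <- estimate_widths(lw[[1]], dw, parw)
  expect_true(all(ww$points$width_left == 7.5))
  expect_true(all(ww$points$width_right == 7.5))

  # edgeless Gaussian ridge: widths equal the gradient-extrema separation
  s <- 4; sg <- 2.31
  gimg <- gaussian_line_image(n = 81, s = s, amp = 0.5)
  pg <- ridge_params(sigma = sg, line_width = 30, upper = 0.05)
  dg <- gaussian_derivatives(gimg, sg)
  lg <- link_ridges(detect_line_points(dg, pg), pg)
  wg <- estimate_widths(lg[[1]], dg, pg)
  expect_equal(wg$mean_width, 2 * sqrt(s^2 + sg^2), tolerance = 0.93)
})

test_that("the line-envelope mask sweeps the expected area", {
  roi <- matrix(TRUE, 120, 120)
  pts <- data.frame(row = 51L, col = 11:111, x = 10:110, y = 50.3,
                    nx = 0, ny = 1, saliency = 1, t = 0,
                    width_left = 5, width_right = 5)
  line <- structure(list(points = pts, length = 100), class = "ridge_line")
  mask <- sd_mask_from_ridges(list(line), roi, "line-envelope",
                              ridge_params(line_width = 15))
  expect_equal(sum(mask), 1000, tolerance = 0.05)
  expect_equal(sum(sd_mask_from_ridges(list(), roi)), 0)
  expect_error(sd_mask_from_ridges(list(line), roi & FALSE), "empty ROI")
})

test_that("the inter-ridge mask fills between paired centerlines only", {
  roi <- matrix(TRUE, 100, 100)
  mk_line <- function(y) {
    pts <- data.frame(row = as.integer(y + 1), col = 11:91, x = 10:90, y = y,
                      nx = 0, ny = 1, saliency = 1, t = 0,
                      width_left = 0, width_right = 0)
    structure(list(points = pts, length = 80), class = "ridge_line")
  }
  # two lines 10 px apart (paired), a third 60 px away (unpaired)
  lines <- list(mk_line(30), mk_line(40), mk_line(95))
  mask <- sd_mask_from_ridges(lines, roi, "inter-ridge",
                              ridge_params(line_width = 15))
  between <- mask[32:40, 20:80]
  expect_true(mean(between) > 0.95)
  expect_equal(sum(mask[60:90, ]), 0)  # nothing filled toward the far line
})

test_that("ridge SD fraction is deterministic and null on flat images", {
  flat <- calibrated_image(matrix(0.5, 80, 80), 0.01)
  roi <- full_roi(c(80, 80), margin = 5)
  expect_equal(sd_fraction_by_ridge(flat, roi)$sd_fraction, 0)

  pat <- cohort_scale_pattern(30, size = 250L)
  roi2 <- full_roi(pat$image, margin = 20)
  m1 <- sd_fraction_by_ridge(pat$image, roi2,
                             params = simulated_ridge_params(0.01))
  m2 <- sd_fraction_by_ridge(pat$image, roi2,
                             params = simulated_ridge_params(0.01))
  expect_identical(m1$sd_fraction, m2$sd_fraction)
  expect_identical(m1$sd_mask, m2$sd_mask)
})

test_that("detected SD mask overlaps the true slit mask", {
  pat <- cohort_scale_pattern(30)
  roi <- full_roi(pat$image, margin = 25)
  roi_mask <- rasterize_roi(roi, dim(pat$image$pixels))
  m <- sd_fraction_by_ridge(pat$image, roi,
                            params = simulated_ridge_params(0.01))
  truth <- pat$truth$slit_mask & roi_mask
  jac <- sum(m$sd_mask & truth) / sum(m$sd_mask | truth)
  expect_gte(jac, 0.6)
})

test_that("SD fraction is robust to image rotation", {
  pat <- cohort_scale_pattern(30, size = 300L)
  roi <- full_roi(c(300, 300), margin = 25)
  pars <- simulated_ridge_params(0.01)
  f0 <- sd_fraction_by_ridge(pat$image, roi, params = pars)$sd_fraction
  rot <- calibrated_image(t(pat$image$pixels)[300:1, ], 0.01)
  f90 <- sd_fraction_by_ridge(rot, roi, params = pars)$sd_fraction
  expect_lt(abs(f90 - f0), 2)

  pat30 <- cohort_scale_pattern(30, size = 300L, orientation = 30)
  f30 <- sd_fraction_by_ridge(pat30$image, roi, params = pars)$sd_fraction
  expect_lt(abs(f30 - f0), 3)
})

test_that("parameter sweeps rank the matched detection scale first", {
  pat <- cohort_scale_pattern(30, size = 300L, noise_sd = 0)
  item <- list(image = pat$image, roi = full_roi(c(300, 300), margin = 25),
               slit_mask = pat$truth$slit_mask)

  single <- sweep_parameters(list(item), data.frame(sigma = 5))
  expect_equal(nrow(single), 1)
  expect_false(single$degenerate)

  grid <- data.frame(sigma = c(1.5, 5, 12))
  res <- sweep_parameters(list(item),
                          cbind(grid, line_width = 20, upper = 0.17))
  # slit half-width is 7.5 px; the matched scale should rank first
  expect_equal(res$sigma[1], 5)
  expect_true(all(diff(res$J) <= 1e-12))

  # pure noise, no true slit pixels -> flagged degenerate rows
  set.seed(2)
  noise_img <- calibrated_image(matrix(0.5 + rnorm(100 * 100, 0, 0.05),
                                       100, 100), 0.01)
  noise_item <- list(image = noise_img, roi = full_roi(c(100, 100), 10),
                     slit_mask = matrix(FALSE, 100, 100))
  resn <- sweep_parameters(list(noise_item), data.frame(sigma = c(3, 5)))
  expect_true(all(resn$degenerate))
})

test_that("measured SD fraction tracks truth over a 20-40% sweep", {
  fr <- c(20, 25, 30, 35, 40)
  res <- t(vapply(fr, function(f) {
    pat <- cohort_scale_pattern(f)
    roi <- full_roi(pat$image, margin = 25)
    c(truth = roi_truth_fraction(pat, roi),
      meas = sd_fraction_by_ridge(pat$image, roi,
        params = simulated_ridge_params(0.01))$sd_fraction)
  }, c(truth = 0, meas = 0)))
  expect_true(all(diff(res[, "meas"]) > 0))
  expect_gte(cor(res[, "truth"], res[, "meas"], method = "spearman"), 0.99)
  expect_lte(mean(abs(res[, "meas"] - res[, "truth"])), 4)
})
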