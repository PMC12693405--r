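test_that("per-mouse aggregation is an order-invariant group mean", {
  st <- data.frame(image_id = c("i1", "i2", "i3"),
                   mouse_id = "m1", group = "non-DN")
  meas <- data.frame(image_id = c("i1", "i2", "i3"), value = c(30, 32, 34))
  expect_equal(aggregate_per_mouse(meas, st)$value, 32)

  set.seed(8)
  n_mice <- 32
  st2 <- data.frame(image_id = sprintf("img%03d", 1:(n_mice * 4)),
                    mouse_id = rep(sprintf("m%02d", 1:n_mice), each = 4),
                    group = rep(c("non-DN", "STZ-DN"), c(17 * 4, 15 * 4)))
  meas2 <- data.frame(image_id = st2$image_id,
                      value = rnorm(nrow(st2), 30, 3))
  agg <- aggregate_per_mouse(meas2, st2)
  expect_equal(nrow(agg), 32)
  oracle <- tapply(meas2$value, st2$mouse_id, mean)
  expect_equal(agg$value, as.numeric(oracle[agg$mouse_id]))

  perm <- sample(nrow(meas2))
  expect_identical(aggregate_per_mouse(meas2[perm, ], st2), agg)

  expect_error(aggregate_per_mouse(
    data.frame(image_id = "nope", value = 1), st2), "no study-table entry")
})

test_that("pooled t-test matches hand computation", {
  same <- c(3, 4, 5)
  r <- two_sample_test(same, same)
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)

  r2 <- two_sample_test(c(1, 2, 3), c(4, 5, 6))
  # pooled sd = 1, se = sqrt(2/3), t = -3 / 0.8165
  expect_equal(r2$t, -3 / sqrt(2 / 3), tolerance = 1e-6)
  expect_equal(r2$df, 4)
  expect_equal(r2$p, 2 * pt(-3 / sqrt(2 / 3), 4), tolerance = 1e-9)
  expect_lt(abs(r2$p - 0.0214), 2e-4)

  expect_error(two_sample_test(c(1, 1), c(1, 1)), "zero variance")
})

test_that("Hedges' g follows the corrected standardized difference", {
  g <- hedges_g(17, 32.00, 2.08, 15, 29.82, 1.98)
  expect_equal(g$correction, 1 - 3 / (4 * 32 - 9))
  expect_equal(g$g, g$correction * g$d)
  expect_gt(abs(g$d), abs(g$g))  # |g| < |d| always

  eq <- hedges_g(10, 5, 1, 12, 5, 1.2)
  expect_equal(eq$g, 0)

  sw <- hedges_g(15, 29.82, 1.98, 17, 32.00, 2.08)
  expect_equal(sw$g, -g$g)
  expect_equal(sw$ci95, -rev(g$ci95))

  # correction factor approaches 1 with N
  expect_gt(hedges_g(500, 1, 1, 500, 0, 1)$correction, 0.999)
  expect_error(hedges_g(5, 1, 0, 5, 1, 0), "pooled")
})

test_that("t-based mean CIs match the closed form", {
  ci <- mean_ci(10, 2, 16)
  expect_equal(ci, 10 + c(-1, 1) * qt(0.975, 15) * 2 / 4)
  expect_equal(mean_ci(5, 0, 10), c(5, 5))
  expect_error(mean_ci(5, 1, 1), "n >= 2")
})

test_that("empirical ROC matches brute-force pair counting", {
  # perfectly separated, lower scores diseased
  r <- empirical_roc(c(1, 2, 3, 10, 11, 12), c(1, 1, 1, 0, 0, 0) == 1,
                     direction = "lower")
  expect_equal(r$auc, 1)

  r2 <- empirical_roc(c(1, 2, 3, 4), c(0, 0, 1, 1) == 1, direction = "higher")
  expect_equal(r2$auc, 1)
  r3 <- empirical_roc(c(1, 2, 3, 4), c(0, 1, 0, 1) == 1, direction = "higher")
  expect_equal(r3$auc, 0.75)

  set.seed(21)
  for (k in 1:25) {
    n <- sample(c(6, 20, 80, 200), 1)
    scores <- sample(1:12, n, TRUE)  # heavy ties
    labels <- sample(c(TRUE, FALSE), n, TRUE)
    if (!any(labels) || all(labels)) next
    dirn <- sample(c("lower", "higher"), 1)
    r <- empirical_roc(scores, labels, dirn)
    expect_equal(r$auc, auc_pairs_oracle(scores, labels, dirn))
    # curve monotone nondecreasing in both coordinates
    expect_true(all(diff(r$curve$fpr) >= 0))
    expect_true(all(diff(r$curve$tpr) >= 0))
  }

  # independent cross-check against pROC on a continuous example
  set.seed(3)
  sc <- rnorm(60); lb <- rep(c(TRUE, FALSE), 30)
  r <- empirical_roc(sc, lb, "higher")
  ref <- as.numeric(pROC::auc(pROC::roc(response = lb, predictor = sc,
                                        direction = "<", quiet = TRUE)))
  expect_equal(r$auc, ref, tolerance = 1e-12)

  # permuted labels on random scores concentrate near 1/2
  set.seed(4)
  rnull <- empirical_roc(rnorm(1000), sample(rep(c(TRUE, FALSE), 500)))
  expect_lt(abs(rnull$auc - 0.5), 0.05)

  expect_error(empirical_roc(1:4, rep(TRUE, 4)), "both classes")
})

test_that("Youden optimum matches exhaustive cutpoint search", {
  # perfect separation
  r <- empirical_roc(c(1, 2, 8, 9), c(TRUE, TRUE, FALSE, FALSE), "lower")
  y <- youden_optimal(r)
  expect_equal(y$j, 1)
  expect_equal(y$threshold, 5)  # midpoint of the straddling scores

  # 6-point hand-built set vs brute force over all cutpoints
  scores <- c(1, 3, 4, 6, 7, 9)
  labels <- c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE)
  r2 <- empirical_roc(scores, labels, "lower")
  y2 <- youden_optimal(r2)
  briefly <- vapply(sort(unique(scores)), function(cut) {
    sens <- mean(scores[labels] <= cut)
    spec <- mean(scores[!labels] > cut)
    sens + spec - 1
  }, 0)
  expect_equal(y2$j, max(briefly))
})

test_that("Wilson intervals reproduce closed-form bounds and monotonicity", {
  ci <- wilson_ci(14, 15)
  z <- qnorm(0.975); p <- 14 / 15; n <- 15
  lower <- (p + z^2 / (2 * n) - z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))) /
    (1 + z^2 / n)
  expect_equal(ci[1], lower, tolerance = 1e-12)
  expect_equal(wilson_ci(0, 20)[1], 0)
  expect_equal(wilson_ci(20, 20)[2], 1)

  lows <- vapply(0:20, function(s) wilson_ci(s, 20)[1], 0)
  expect_true(all(diff(lows) >= 0))
  expect_error(wilson_ci(5, 0), "trials")
})

test_that("correlation and regression match direct formulas", {
  x <- c(1, 2, 4, 7, 9)
  expect_equal(pearson_corr(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_corr(x, -x)$r, -1)

  y <- c(2.2, 1.8, 5.1, 6.0, 9.7)
  r <- pearson_corr(x, y)
  r_direct <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(r$r, r_direct, tolerance = 1e-12)
  expect_error(pearson_corr(x, rep(1, 5)), "zero variance")

  f <- linear_fit(c(0, 1, 2, 3), c(1, 3, 5, 7))
  expect_equal(f$slope, 2); expect_equal(f$intercept, 1)
  expect_equal(f$r_squared, 1)

  x4 <- c(0, 1, 2, 4); y4 <- c(1.1, 1.9, 3.2, 4.8)
  f4 <- linear_fit(x4, y4)
  X <- cbind(1, x4)
  beta <- solve(t(X) %*% X, t(X) %*% y4)
  expect_equal(c(f4$intercept, f4$slope), as.numeric(beta), tolerance = 1e-12)
  expect_error(linear_fit(rep(2, 4), y4), "zero variance")
})

test_that("Bland-Altman bias and limits follow the sample-SD convention", {
  a <- c(30, 31, 29.5, 32)
  r <- bland_altman(a, a)
  expect_equal(r$bias, 0); expect_equal(r$loa, c(0, 0))

  r2 <- bland_altman(c(1, 0), c(0, 1))  # d = {1, -1}
  expect_equal(r2$bias, 0)
  expect_equal(r2$loa, c(-1.96, 1.96) * sqrt(2))

  r3 <- bland_altman(a, c(29, 30, 30, 31))
  r3s <- bland_altman(c(29, 30, 30, 31), a)
  expect_equal(r3s$bias, -r3$bias)
  expect_equal(r3s$loa, -rev(r3$loa))
  expect_equal(nrow(r3$pairs), 4)

  # 20 simulated rater pairs with difference SD 1.9: LoA width near
  # 2 * 1.96 * 1.9, within the sampling error of an SD at n = 20
  set.seed(12)
  truth <- runif(20, 25, 35)
  widths <- replicate(50, {
    r <- bland_altman(truth + rnorm(20, 0, 1.9 / sqrt(2)),
                      truth + rnorm(20, 0, 1.9 / sqrt(2)))
    diff(r$loa)
  })
  expect_equal(mean(widths), 2 * 1.96 * 1.9, tolerance = 0.1 * 2 * 1.96 * 1.9)
  expect_error(bland_altman(1:3, 1:4), "equal length")
})
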