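# Cohort-level statistical evaluation: per-mouse aggregation, group
# comparison, effect size, ROC/Youden with Wilson intervals, correlation,
# regression, and Bland-Altman agreement.

#' Aggregate per-image measurements to per-mouse means
#'
#' The per-mouse value is the unweighted mean of that mouse's per-image
#' values, with the group label attached; the result is invariant to row
#' order.
#'
#' @param measurements data.frame with columns `image_id` and `value`.
#' @param study_table data.frame mapping `image_id` to `mouse_id` and
#'   `group` (and optional covariates, carried through per mouse).
#' @return data.frame with one row per mouse: `mouse_id`, `group`, `value`,
#'   `n_images`, plus any mouse-constant covariates.
#' @export
aggregate_per_mouse <- function(measurements, study_table) {
  merged <- merge(measurements, study_table, by = "image_id")
  if (nrow(merged) < nrow(measurements)) {
    stop("some measurements have no study-table entry")
  }
  split_rows <- split(merged, merged$mouse_id)
  out <- lapply(split_rows, function(d) {
    if (length(unique(d$group)) != 1L) {
      stop("group label not constant within mouse ", d$mouse_id[1])
    }
    row <- data.frame(mouse_id = d$mouse_id[1], group = d$group[1],
                      value = mean(d$value), n_images = nrow(d),
                      stringsAsFactors = FALSE)
    for (cov in intersect(c("fasting_glucose", "acr"), names(d))) {
      row[[cov]] <- mean(d[[cov]])
    }
    row
  })
  res <- do.call(rbind, out)
  res <- res[order(res$mouse_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Unpaired two-tailed t-test
#'
#' Student's pooled-variance test by default (the published analysis used
#' plain unpaired two-tailed t-tests); Welch's correction by flag.
#'
#' @param x,y numeric vectors (each n >= 2).
#' @param welch use Welch's unequal-variance test.
#' @return List with `t`, `df`, `p`.
#' @export
two_sample_test <- function(x, y, welch = FALSE) {
  if (length(x) < 2L || length(y) < 2L) stop("each group needs n >= 2")
  if (var(x) == 0 && var(y) == 0 && mean(x) == mean(y)) {
    stop("zero variance in both groups with equal means")
  }
  fit <- t.test(x, y, var.equal = !welch)
  list(t = unname(fit$statistic), df = unname(fit$parameter),
       p = fit$p.value)
}

#' Group summary with t-based confidence interval
#'
#' @param x numeric vector (n >= 2).
#' @param level confidence level.
#' @return List with `n`, `mean`, `sd`, `ci95 = c(low, high)`.
#' @export
group_summary <- function(x, level = 0.95) {
  n <- length(x)
  if (n < 2L) stop("need n >= 2")
  list(n = n, mean = mean(x), sd = sd(x),
       ci95 = mean_ci(mean(x), sd(x), n, level))
}

#' t-based confidence interval for a mean
#'
#' `mean +- t(1 - alpha/2, n - 1) * sd / sqrt(n)`.
#'
#' @param mean,sd,n summary statistics (n >= 2, sd >= 0).
#' @param level confidence level (default 0.95).
#' @return `c(low, high)`.
#' @export
mean_ci <- function(mean, sd, n, level = 0.95) {
  if (n < 2L) stop("need n >= 2")
  if (sd < 0) stop("sd must be nonnegative")
  half <- qt(1 - (1 - level) / 2, df = n - 1) * sd / sqrt(n)
  c(mean - half, mean + half)
}

#' Hedges' g standardized mean difference from group summaries
#'
#' `d = (mean1 - mean2) / s_pooled` with the pooled SD over `n1 + n2 - 2`
#' degrees of freedom, small-sample correction
#' `J = 1 - 3 / (4 N - 9)` (N = n1 + n2), and `g = J * d`. The default
#' confidence interval is the normal-approximation interval computed on `d`
#' and then scaled by `J` (`ci_on = "d"`); `ci_on = "g"` gives the common
#' alternative computed directly on `g`.
#'
#' @param n1,mean1,sd1,n2,mean2,sd2 group summaries (n >= 2 each).
#' @param level confidence level.
#' @param ci_on `"d"` (default) or `"g"`.
#' @return List with `g`, `ci95`, `d`, `pooled_sd`, `correction`, `se_d`.
#' @export
hedges_g <- function(n1, mean1, sd1, n2, mean2, sd2, level = 0.95,
                     ci_on = c("d", "g")) {
  ci_on <- match.arg(ci_on)
  if (n1 < 2L || n2 < 2L) stop("need n >= 2 in each group")
  sp <- sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2))
  if (sp == 0) stop("zero pooled standard deviation")
  d <- (mean1 - mean2) / sp
  N <- n1 + n2
  J <- 1 - 3 / (4 * N - 9)
  g <- J * d
  z <- qnorm(1 - (1 - level) / 2)
  se_d <- sqrt(N / (n1 * n2) + d^2 / (2 * N))
  ci <- if (ci_on == "d") {
    J * c(d - z * se_d, d + z * se_d)
  } else {
    se_g <- J * se_d
    c(g - z * se_g, g + z * se_g)
  }
  list(g = g, ci95 = ci, d = d, pooled_sd = sp, correction = J, se_d = se_d)
}

#' Empirical ROC curve
#'
#' Curve over all distinct score thresholds; AUC by the trapezoid rule,
#' which equals the Mann-Whitney pair statistic with ties counted one half.
#' With `direction = "lower"` (the SD-fraction convention: diseased mice
#' have lower scores) a case is called positive when its score is at or
#' below the threshold.
#'
#' @param scores numeric scores (e.g., per-mouse SD fraction).
#' @param labels logical or 0/1 vector; `TRUE`/1 = positive class (diseased).
#' @param direction `"lower"` (default) if positives have lower scores,
#'   `"higher"` otherwise.
#' @return List of class `roc_result`: `auc`, `curve` (data.frame
#'   `threshold`, `fpr`, `tpr`), `direction`, `n_pos`, `n_neg`,
#'   `scores`, `labels`.
#' @export
empirical_roc <- function(scores, labels, direction = c("lower", "higher")) {
  direction <- match.arg(direction)
  labels <- as.logical(labels)
  if (!any(labels) || all(labels)) stop("both classes must be present")
  if (length(scores) != length(labels)) stop("length mismatch")
  s <- if (direction == "lower") -scores else scores
  # positive call: s >= threshold (in oriented score space)
  thr <- sort(unique(s), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(s[labels] >= t), 0)
  fpr <- vapply(thr, function(t) mean(s[!labels] >= t), 0)
  curve <- data.frame(threshold = c(NA, if (direction == "lower") -thr else thr),
                      fpr = c(0, fpr), tpr = c(0, tpr))
  auc <- sum(diff(curve$fpr) * (head(curve$tpr, -1) + tail(curve$tpr, -1)) / 2)
  structure(list(auc = auc, curve = curve, direction = direction,
                 n_pos = sum(labels), n_neg = sum(!labels),
                 scores = scores, labels = labels),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC %.4f (%d pos / %d neg, direction: %s)\n",
              x$auc, x$n_pos, x$n_neg, x$direction))
  invisible(x)
}

#' Optimal threshold by the Youden index
#'
#' `J = max(tpr - fpr)` over the ROC curve. The reported threshold is the
#' midpoint between the adjacent observed scores straddling the optimal
#' cut; ties are broken toward higher specificity. Sensitivity and
#' specificity at the optimum carry Wilson 95% intervals.
#'
#' @param roc a `roc_result` from [empirical_roc()].
#' @return List with `threshold`, `j`, `sensitivity`, `specificity`,
#'   `sensitivity_ci`, `specificity_ci` (Wilson, proportions).
#' @export
youden_optimal <- function(roc) {
  curve <- roc$curve[-1, , drop = FALSE]  # drop the (0,0) anchor
  j_all <- curve$tpr - curve$fpr
  best <- which(j_all == max(j_all))
  # ties toward higher specificity (lower fpr)
  best <- best[which.min(curve$fpr[best])]
  thr_curve <- curve$threshold[best]
  s <- roc$scores
  pos_call <- if (roc$direction == "lower") s <= thr_curve else s >= thr_curve
  # midpoint between the straddling observed scores
  inside <- if (roc$direction == "lower") max(s[pos_call]) else min(s[pos_call])
  outside_cand <- if (roc$direction == "lower") s[s > inside] else s[s < inside]
  threshold <- if (length(outside_cand)) (inside + if (roc$direction == "lower")
    min(outside_cand) else max(outside_cand)) / 2 else inside
  tp <- sum(pos_call & roc$labels); fn <- sum(!pos_call & roc$labels)
  tn <- sum(!pos_call & !roc$labels); fp <- sum(pos_call & !roc$labels)
  list(threshold = threshold, j = max(j_all),
       sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
       sensitivity_ci = wilson_ci(tp, tp + fn),
       specificity_ci = wilson_ci(tn, tn + fp))
}

#' Wilson score confidence interval for a binomial proportion
#'
#' @param successes,trials counts, `0 <= successes <= trials`, `trials >= 1`.
#' @param level confidence level.
#' @return `c(low, high)`, both in `[0, 1]`.
#' @export
wilson_ci <- function(successes, trials, level = 0.95) {
  if (trials < 1L) stop("trials must be >= 1")
  if (successes < 0 || successes > trials) stop("invalid success count")
  z <- qnorm(1 - (1 - level) / 2)
  p <- successes / trials
  denom <- 1 + z^2 / trials
  center <- (p + z^2 / (2 * trials)) / denom
  half <- z * sqrt(p * (1 - p) / trials + z^2 / (4 * trials^2)) / denom
  c(max(0, center - half), min(1, center + half))
}

#' Pearson correlation with two-sided p-value
#'
#' @param x,y numeric vectors, n >= 3, finite.
#' @return List with `r`, `p`, `n`.
#' @export
pearson_corr <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  if (length(x) < 3L) stop("need n >= 3")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("values must be finite")
  if (var(x) == 0 || var(y) == 0) stop("zero variance")
  fit <- cor.test(x, y, method = "pearson")
  list(r = unname(fit$estimate), p = fit$p.value, n = length(x))
}

#' Simple linear regression
#'
#' @param x,y numeric vectors, n >= 3.
#' @return List with `slope`, `intercept`, `r_squared`.
#' @export
linear_fit <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  if (length(x) < 3L) stop("need n >= 3")
  if (var(x) == 0) stop("zero variance in x")
  fit <- lm(y ~ x)
  ss_res <- sum(residuals(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else 1)
}

#' Bland-Altman agreement analysis
#'
#' Differences `d = a - b`; bias = mean(d); 95% limits of agreement
#' `bias +- 1.96 * sd(d)` (sample SD). Per-pair `(mean, difference)` rows
#' are returned for plotting.
#'
#' @param a,b paired measurement vectors of equal length >= 2.
#' @return List of class `agreement_report`: `bias`, `loa = c(low, high)`,
#'   `sd_diff`, `n`, `pairs` (data.frame `mean`, `difference`).
#' @export
bland_altman <- function(a, b) {
  if (length(a) != length(b)) stop("paired vectors must have equal length")
  if (length(a) < 2L) stop("need at least 2 pairs")
  d <- a - b
  bias <- mean(d)
  sdd <- sd(d)
  structure(list(bias = bias, loa = c(bias - 1.96 * sdd, bias + 1.96 * sdd),
                 sd_diff = sdd, n = length(d),
                 pairs = data.frame(mean = (a + b) / 2, difference = d)),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("<agreement_report> bias %.3f, 95%% LoA [%.3f, %.3f] (n = %d)\n",
              x$bias, x$loa[1], x$loa[2], x$n))
  invisible(x)
}
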