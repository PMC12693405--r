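# Orchestration: measure -> aggregate -> statistics as one reproducible run.

#' Default run configuration
#'
#' The `published` profile embeds the published parameter set: blur
#' radii 2.00 (threshold) / 4.00 (ridge); ridge sigma 5.70, line width 15,
#' thresholds 0.00 / 0.17, minimum line length 5.00, maximum line length
#' 0.00 (unbounded). The `simulated` profile swaps in the simulator-matched
#' detection parameters ([simulated_ridge_params()]).
#'
#' @param profile `"published"` or `"simulated"`.
#' @param scale micrometers per pixel, used by the `"simulated"` profile to
#'   convert its physical detection lengths to pixels.
#' @return Nested parameter list.
#' @export
default_config <- function(profile = c("published", "simulated"),
                           scale = 0.01) {
  profile <- match.arg(profile)
  list(
    profile = profile,
    threshold = list(blur_radius = 2.0, polarity = "dark", n_bins = 256L),
    ridge = c(list(blur_radius = 4.0, mode = "line-envelope",
                   polarity = "dark"),
              unclass(if (profile == "simulated") simulated_ridge_params(scale)
                      else ridge_params())),
    profile_method = list(min_prominence = 0.35, min_separation = 0.1,
                          polarity = "bright", n_lines = 3L)
  )
}

ridge_params_from_config <- function(cfg) {
  ridge_params(sigma = cfg$sigma, line_width = cfg$line_width,
               lower = cfg$lower, upper = cfg$upper,
               min_len = cfg$min_len, max_len = cfg$max_len)
}

# Evenly spaced horizontal profile lines spanning the ROI interior --
# the simulator draws slits near-vertical, so horizontal lines cross
# multiple foot processes as the annotation protocol requires.
default_profile_lines <- function(image, roi, n_lines = 3L) {
  v <- roi$vertices
  x0 <- min(v[, 1]) + 1; x1 <- max(v[, 1]) - 1
  y0 <- min(v[, 2]); y1 <- max(v[, 2])
  ys <- y0 + (seq_len(n_lines) / (n_lines + 1)) * (y1 - y0)
  lapply(seq_len(n_lines), function(i) {
    polyline_roi(rbind(c(x0, ys[i]), c(x1, ys[i])),
                 label = sprintf("line_%d", i))
  })
}

#' Measure every image of a cohort
#'
#' @param cohort an in-memory cohort from [simulate_cohort()] or
#'   [load_cohort()].
#' @param methods subset of `c("threshold", "ridge", "profile")`.
#' @param config parameter list from [default_config()].
#' @return data.frame of per-image rows: `image_id`, `mouse_id`, `group`,
#'   `method`, `value`, `units`.
#' @export
measure_cohort <- function(cohort, methods = c("threshold", "ridge"),
                           config = default_config("simulated")) {
  rows <- list()
  rp <- ridge_params_from_config(config$ridge)
  for (item in cohort$images) {
    for (method in methods) {
      val <- units <- NULL
      if (method == "threshold") {
        m <- sd_fraction_by_threshold(
          item$image, item$roi, blur_radius = config$threshold$blur_radius,
          polarity = config$threshold$polarity,
          n_bins = config$threshold$n_bins)
        val <- m$sd_fraction; units <- "percent"
      } else if (method == "ridge") {
        m <- sd_fraction_by_ridge(
          item$image, item$roi, blur_radius = config$ridge$blur_radius,
          params = rp, mode = config$ridge$mode,
          polarity = config$ridge$polarity)
        val <- m$sd_fraction; units <- "percent"
      } else if (method == "profile") {
        pm <- config$profile_method
        lines <- item$lines %||%
          default_profile_lines(item$image, item$roi, pm$n_lines)
        profs <- lapply(lines, function(ln) {
          measure_profile(sample_profile(item$image, ln),
                          min_prominence = pm$min_prominence,
                          min_separation = pm$min_separation,
                          polarity = pm$polarity,
                          source_id = item$image_id, roi_label = ln$label)
        })
        val <- suppressWarnings(fpw_from_profiles(profs)); units <- "um"
      } else {
        stop("unknown method: ", method)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        image_id = item$image_id, mouse_id = item$mouse_id,
        group = item$group, method = method, value = val, units = units,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Load a cohort written by [write_cohort()]
#'
#' @param dir directory with TIFFs, .roi files, and `study_table.csv`.
#' @param scale micrometers per pixel for the images.
#' @return A cohort list compatible with [measure_cohort()].
#' @export
load_cohort <- function(dir, scale) {
  st_path <- file.path(dir, "study_table.csv")
  if (!file.exists(st_path)) stop("missing study_table.csv in ", dir)
  study <- read_measurements(st_path)
  images <- lapply(seq_len(nrow(study)), function(i) {
    id <- study$image_id[i]
    tif <- file.path(dir, paste0(id, ".tif"))
    roi_f <- file.path(dir, paste0(id, ".roi"))
    if (!file.exists(tif)) stop("manifest references missing image: ", tif)
    if (!file.exists(roi_f)) stop("manifest references missing ROI: ", roi_f)
    list(image = load_image(tif, scale, source_id = id),
         roi = read_rois(roi_f, "imagej-roi")[[1]],
         image_id = id, glomerulus_id = study$glomerulus_id[i],
         mouse_id = study$mouse_id[i], group = study$group[i])
  })
  list(images = images, study_table = study)
}

#' Cohort-level statistics for one measurement method
#'
#' Reproduces the study's evaluation: per-group summaries with t-based
#' CIs, pooled-variance t-test, Hedges' g, empirical ROC with Youden-optimal
#' threshold and Wilson intervals, and (when covariates are present)
#' Pearson correlations with fasting glucose and ACR.
#'
#' @param per_mouse data.frame from [aggregate_per_mouse()].
#' @param positive_group label of the diseased group (default `"STZ-DN"`).
#' @param direction `"lower"` if disease lowers the score.
#' @return List of class `diagnostic_report`.
#' @export
study_statistics <- function(per_mouse, positive_group = "STZ-DN",
                             direction = "lower") {
  groups <- unique(per_mouse$group)
  if (length(groups) != 2L) stop("need exactly two groups")
  neg_group <- setdiff(groups, positive_group)
  x_neg <- per_mouse$value[per_mouse$group == neg_group]
  x_pos <- per_mouse$value[per_mouse$group == positive_group]
  if (length(x_neg) < 2L || length(x_pos) < 2L) {
    warning("fewer than 2 mice in a group: summaries only, tests skipped")
    smry <- function(x) list(n = length(x), mean = mean(x),
                             sd = if (length(x) > 1L) sd(x) else NA_real_,
                             ci95 = c(NA_real_, NA_real_))
    report <- list(groups = stats::setNames(list(smry(x_neg), smry(x_pos)),
                                            c(neg_group, positive_group)))
    class(report) <- "diagnostic_report"
    return(report)
  }
  report <- list(
    groups = stats::setNames(list(group_summary(x_neg), group_summary(x_pos)),
                             c(neg_group, positive_group)),
    t_test = two_sample_test(x_neg, x_pos),
    effect_size = hedges_g(length(x_neg), mean(x_neg), sd(x_neg),
                           length(x_pos), mean(x_pos), sd(x_pos))
  )
  roc <- empirical_roc(per_mouse$value, per_mouse$group == positive_group,
                       direction = direction)
  report$roc <- roc
  report$youden <- youden_optimal(roc)
  for (cov in intersect(c("fasting_glucose", "acr"), names(per_mouse))) {
    report$correlations[[cov]] <-
      pearson_corr(per_mouse$value, per_mouse[[cov]])
  }
  class(report) <- "diagnostic_report"
  report
}

#' @export
print.diagnostic_report <- function(x, ...) {
  for (g in names(x$groups)) {
    s <- x$groups[[g]]
    cat(sprintf("%-8s n=%2d  mean %.2f +- %.2f  95%% CI [%.2f, %.2f]\n",
                g, s$n, s$mean, s$sd, s$ci95[1], s$ci95[2]))
  }
  if (is.null(x$t_test)) return(invisible(x))
  cat(sprintf("t = %.3f (df %.1f), p = %.4g\n", x$t_test$t, x$t_test$df,
              x$t_test$p))
  cat(sprintf("Hedges' g = %.2f, 95%% CI [%.2f, %.2f]\n", x$effect_size$g,
              x$effect_size$ci95[1], x$effect_size$ci95[2]))
  cat(sprintf("AUC = %.4f; Youden J = %.2f at threshold %.2f\n",
              x$roc$auc, x$youden$j, x$youden$threshold))
  cat(sprintf("sensitivity %.0f%% [%.2f, %.2f]%%, specificity %.0f%% [%.2f, %.2f]%%\n",
              100 * x$youden$sensitivity, 100 * x$youden$sensitivity_ci[1],
              100 * x$youden$sensitivity_ci[2], 100 * x$youden$specificity,
              100 * x$youden$specificity_ci[1], 100 * x$youden$specificity_ci[2]))
  for (cov in names(x$correlations)) {
    cc <- x$correlations[[cov]]
    cat(sprintf("correlation with %s: R = %.2f (n = %d, p = %.4g)\n",
                cov, cc$r, cc$n, cc$p))
  }
  invisible(x)
}

#' Run a full study: measure, aggregate, evaluate
#'
#' @param cohort in-memory cohort ([simulate_cohort()] / [load_cohort()]).
#' @param methods measurement methods to run.
#' @param config parameter list from [default_config()].
#' @param out_dir optional output directory; when given, writes
#'   `per_image.csv`, `per_mouse_<method>.csv`, `report_<method>.yaml`, and
#'   a `run_manifest.yaml` recording all parameters and the package version.
#' @return List with `per_image`, `per_mouse` (per method), `reports` (per
#'   method), `config`.
#' @export
run_study <- function(cohort, methods = c("threshold", "ridge"),
                      config = default_config("simulated"),
                      out_dir = NULL) {
  per_image <- measure_cohort(cohort, methods, config)
  study_cols <- cohort$study_table
  if (!is.null(cohort$mouse_table)) {
    study_cols <- merge(study_cols,
                        cohort$mouse_table[, setdiff(names(cohort$mouse_table),
                                                     c("group")), drop = FALSE],
                        by = "mouse_id")
  }
  per_mouse <- list()
  reports <- list()
  for (method in methods) {
    rows <- per_image[per_image$method == method, , drop = FALSE]
    pm <- aggregate_per_mouse(rows[, c("image_id", "value")], study_cols)
    per_mouse[[method]] <- pm
    reports[[method]] <- study_statistics(
      pm, direction = if (method == "profile") "higher" else "lower")
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_measurements(per_image, file.path(out_dir, "per_image.csv"))
    for (method in methods) {
      write_measurements(per_mouse[[method]],
                         file.path(out_dir, sprintf("per_mouse_%s.csv", method)))
      yaml::write_yaml(report_to_list(reports[[method]]),
                       file.path(out_dir, sprintf("report_%s.yaml", method)))
    }
    manifest <- list(package = "podosem",
                     version = as.character(utils::packageVersion("podosem")),
                     methods = methods, config = config)
    yaml::write_yaml(manifest, file.path(out_dir, "run_manifest.yaml"))
  }
  list(per_image = per_image, per_mouse = per_mouse, reports = reports,
       config = config)
}

report_to_list <- function(report) {
  list(
    groups = lapply(report$groups, function(s)
      list(n = s$n, mean = s$mean, sd = s$sd, ci95 = as.numeric(s$ci95))),
    t_test = report$t_test,
    effect_size = list(g = report$effect_size$g,
                       ci95 = as.numeric(report$effect_size$ci95)),
    auc = report$roc$auc,
    youden = list(j = report$youden$j, threshold = report$youden$threshold,
                  sensitivity = report$youden$sensitivity,
                  specificity = report$youden$specificity,
                  sensitivity_ci = as.numeric(report$youden$sensitivity_ci),
                  specificity_ci = as.numeric(report$youden$specificity_ci)),
    correlations = lapply(report$correlations, function(cc)
      list(r = cc$r, p = cc$p, n = cc$n))
  )
}

#' Side-by-side comparison of the three methods
#'
#' One wide per-mouse table (SD% by thresholding, SD% by ridge detection,
#' FPW by profile) plus the three ROC analyses.
#'
#' @inheritParams run_study
#' @return List with `per_mouse` (wide data.frame) and `reports` (one
#'   `diagnostic_report` per method).
#' @export
compare_methods <- function(cohort, config = default_config("simulated")) {
  if (is.null(cohort$study_table$group)) stop("cohort has no group labels")
  res <- run_study(cohort, methods = c("threshold", "ridge", "profile"),
                   config = config)
  wide <- NULL
  for (method in names(res$per_mouse)) {
    pm <- res$per_mouse[[method]][, c("mouse_id", "group", "value")]
    names(pm)[3] <- method
    wide <- if (is.null(wide)) pm else merge(wide, pm,
                                             by = c("mouse_id", "group"))
  }
  list(per_mouse = wide[order(wide$mouse_id), , drop = FALSE],
       reports = res$reports)
}
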