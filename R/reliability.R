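feature_names <- c("avg_weighted_degree", "avg_path_length",
                   "global_clustering", "n_communities", "modularity")

# Long form (subject [, session], region, feature, value) from a wide
# feature table as produced by feature_table()/cohort_features().
pivot_features <- function(features) {
  cols <- intersect(feature_names, names(features))
  if (length(cols) == 0) {
    abort("no feature columns found", class = "vgfc_error_validation")
  }
  tidyr::pivot_longer(features, all_of(cols), names_to = "feature",
                      values_to = "value")
}

#' Correlation between motion burden and graph features
#'
#' For each (region, feature) pair, the Pearson correlation across subjects
#' between the feature value and the subject's percentage of
#' motion-corrupted frames (FD > 0.2 mm). When `cap_percent` is given,
#' subjects with `pct_corrupted >= cap_percent` are excluded first, so the
#' analysis runs on the low-motion subset only.
#'
#' No multiple-testing correction is applied; `n_subjects` is reported so
#' downstream users can correct as they see fit.
#'
#' @param features feature table with columns `subject`, `region` and the
#'   five feature columns (a single session's worth).
#' @param motion_pct tibble (`subject`, `pct_corrupted`), percentages 0-100.
#' @param cap_percent optional strict upper cap on `pct_corrupted`.
#' @return tibble (`region`, `feature`, `pearson_r`, `n_subjects`). Regions
#'   with fewer than 3 retained subjects are skipped with a warning.
#' @export
motion_feature_correlation <- function(features, motion_pct,
                                       cap_percent = NULL) {
  mp <- select(motion_pct, "subject", "pct_corrupted") |> distinct()
  if (anyDuplicated(mp$subject)) {
    abort("motion_pct must have one row per subject (one session)",
          class = "vgfc_error_validation")
  }
  if (!is.null(cap_percent)) {
    check_scalar(cap_percent, "cap_percent", lower = 0, strict_lower = TRUE)
    mp <- filter(mp, .data$pct_corrupted < cap_percent)
  }
  df <- inner_join(pivot_features(features), mp, by = "subject")
  out <- df |>
    group_by(.data$region, .data$feature) |>
    summarise(n_subjects = dplyr::n_distinct(.data$subject),
              pearson_r = if (dplyr::n_distinct(.data$subject) >= 3 &&
                              sd(.data$value) > 0 && sd(.data$pct_corrupted) > 0)
                cor(.data$value, .data$pct_corrupted) else NA_real_,
              .groups = "drop")
  skipped <- filter(out, .data$n_subjects < 3)
  if (nrow(skipped) > 0) {
    warn(sprintf("%d region/feature cells skipped (fewer than 3 subjects)",
                 nrow(skipped)))
    out <- filter(out, .data$n_subjects >= 3)
  }
  select(out, "region", "feature", "pearson_r", "n_subjects")
}

#' Per-feature summary of motion correlations across regions
#'
#' @param per_region output of [motion_feature_correlation()].
#' @return tibble (`feature`, `mean_r`, `sd_r`, `n_regions`).
#' @export
summarise_motion_impact <- function(per_region) {
  per_region |>
    group_by(.data$feature) |>
    summarise(mean_r = mean(.data$pearson_r, na.rm = TRUE),
              sd_r = sd(.data$pearson_r, na.rm = TRUE),
              n_regions = sum(!is.na(.data$pearson_r)),
              .groups = "drop")
}

#' Motion-cap sweep of the feature-motion correlation
#'
#' Re-runs [motion_feature_correlation()] on nested low-motion subsets: for
#' each cap x in the grid (default 10% to 40% in 0.5% steps, 61 points),
#' only subjects with fewer than x% corrupted frames enter. Tracks how the
#' apparent motion-feature association decays as the sample is restricted
#' to cleaner scans.
#'
#' @inheritParams motion_feature_correlation
#' @param caps cap grid in percent (default `seq(10, 40, by = 0.5)`).
#' @return an object of class `vg_motion_sweep`: a tibble (`cap_percent`,
#'   `feature`, `mean_r_across_regions`, `n_subjects`) with an [autoplot()]
#'   method. Caps whose subset is empty (or universally sub-3) report
#'   `NA` correlations with `n_subjects = 0`.
#' @export
motion_sweep <- function(features, motion_pct, caps = seq(10, 40, by = 0.5)) {
  rows <- purrr::map_dfr(caps, function(cap) {
    n_kept <- sum(motion_pct$pct_corrupted < cap)
    if (n_kept < 3) {
      return(tibble(cap_percent = cap, feature = feature_names,
                    mean_r_across_regions = NA_real_, n_subjects = n_kept))
    }
    per_region <- suppressWarnings(
      motion_feature_correlation(features, motion_pct, cap_percent = cap))
    summarise_motion_impact(per_region) |>
      mutate(cap_percent = cap, n_subjects = n_kept) |>
      select("cap_percent", "feature",
             mean_r_across_regions = "mean_r", "n_subjects")
  })
  structure(arrange(rows, .data$cap_percent, .data$feature),
            class = c("vg_motion_sweep", class(rows)))
}

#' @rdname motion_sweep
#' @param object a `vg_motion_sweep`.
#' @param ... unused.
#' @exportS3Method ggplot2::autoplot
autoplot.vg_motion_sweep <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$cap_percent,
                               y = .data$mean_r_across_regions,
                               colour = .data$feature)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::labs(x = "motion cap (% corrupted frames)",
                  y = "mean Pearson r across regions",
                  colour = NULL,
                  title = "feature-motion correlation vs motion cap") +
    ggplot2::theme_minimal()
}

#' Two-way absolute-agreement intraclass correlation, ICC(A,1)
#'
#' Single-measurement absolute-agreement ICC from the two-way ANOVA
#' decomposition (McGraw & Wong's ICC(A,1), the coefficient recommended for
#' test-retest designs):
#' \deqn{ICC = \frac{MS_R - MS_E}{MS_R + (k-1)MS_E + \frac{k}{n}(MS_C - MS_E)}}
#' with \eqn{MS_R} the between-subjects, \eqn{MS_C} the between-sessions and
#' \eqn{MS_E} the residual mean squares. Absolute agreement charges a
#' constant session offset against reliability, unlike the consistency
#' coefficient. The 95% CI is the McGraw–Wong F-based interval with
#' Satterthwaite degrees of freedom. The mixed- vs random-effects reading of
#' the session factor does not change the point estimate.
#'
#' @param x n x k numeric matrix or data frame, subjects as rows, sessions
#'   as columns (no missing cells; n >= 5 recommended, k = 2 in a
#'   two-session design).
#' @return an object of class `vg_icc` with fields `icc`, `ci95`,
#'   `ms_rows`, `ms_cols`, `ms_error`, `n_subjects`, `k_sessions`.
#'   Has [tidy()] and [glance()] methods.
#' @examples
#' set.seed(1)
#' u <- rnorm(100, sd = sqrt(3))
#' x <- cbind(u + rnorm(100), u + rnorm(100))   # true ICC = 0.75
#' icc_absolute_agreement(x)
#' @export
icc_absolute_agreement <- function(x) {
  x <- as.matrix(x)
  if (anyNA(x)) {
    abort("missing cells are not allowed (no imputation)",
          class = "vgfc_error_validation")
  }
  n <- nrow(x); k <- ncol(x)
  if (n < 2 || k < 2) {
    abort("need at least 2 subjects and 2 sessions",
          class = "vgfc_error_validation")
  }
  if (n < 5) warn("fewer than 5 subjects; ICC will be unstable")
  gm <- mean(x)
  rm_ <- rowMeans(x); cm <- colMeans(x)
  msr <- k * sum((rm_ - gm)^2) / (n - 1)
  msc <- n * sum((cm - gm)^2) / (k - 1)
  sse <- sum((x - outer(rm_, rep(1, k)) - outer(rep(1, n), cm) + gm)^2)
  mse <- sse / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + (k / n) * (msc - mse)
  icc <- if (denom == 0) 1 else (msr - mse) / denom
  ci <- icc_a1_ci(icc, msr, msc, mse, n, k)
  structure(list(icc = icc, ci95 = ci, ms_rows = msr, ms_cols = msc,
                 ms_error = mse, n_subjects = n, k_sessions = k),
            class = "vg_icc")
}

# McGraw & Wong F-based interval for ICC(A,1).
icc_a1_ci <- function(icc, msr, msc, mse, n, k, conf = 0.95) {
  if (mse == 0 && msc == 0) return(c(icc, icc))
  alpha <- 1 - conf
  a <- (k * icc) / (n * (1 - icc))
  b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
  if (!is.finite(a) || !is.finite(b)) return(c(icc, icc))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  f_l <- qf(1 - alpha / 2, n - 1, v)
  f_u <- qf(1 - alpha / 2, v, n - 1)
  lo <- n * (msr - f_l * mse) /
    (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
  hi <- n * (f_u * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f_u * msr)
  c(max(-1, min(lo, icc)), min(1, max(hi, icc)))
}

#' @export
print.vg_icc <- function(x, ...) {
  cat(sprintf("<vg_icc> ICC(A,1) = %.3f, 95%% CI [%.3f, %.3f] (n = %d, k = %d)\n",
              x$icc, x$ci95[1], x$ci95[2], x$n_subjects, x$k_sessions))
  invisible(x)
}

#' @rdname icc_absolute_agreement
#' @param ... unused.
#' @exportS3Method generics::tidy
tidy.vg_icc <- function(x, ...) {
  tibble(term = "icc_a1", estimate = x$icc,
         conf.low = x$ci95[1], conf.high = x$ci95[2])
}

#' @rdname icc_absolute_agreement
#' @exportS3Method generics::glance
glance.vg_icc <- function(x, ...) {
  tibble(icc = x$icc, ci_lo = x$ci95[1], ci_hi = x$ci95[2],
         ms_rows = x$ms_rows, ms_cols = x$ms_cols, ms_error = x$ms_error,
         n_subjects = x$n_subjects, k_sessions = x$k_sessions)
}

#' Test-retest reliability report over a low-motion subset
#'
#' Computes ICC(A,1) between the two sessions for every (region, feature)
#' pair, restricted to subjects whose motion-corrupted percentage is
#' strictly below `cap_percent` in *both* sessions. Subjects present in only
#' one feature table are excluded with a warning.
#'
#' @param features_s1,features_s2 feature tables (columns `subject`,
#'   `region`, five features) for sessions 1 and 2.
#' @param motion_pct tibble (`subject`, `session`, `pct_corrupted`); may be
#'   `NULL` to skip motion screening.
#' @param cap_percent strict cap in percent (default 20).
#' @return tibble (`region`, `feature`, `icc`, `ci_lo`, `ci_hi`,
#'   `n_subjects`).
#' @export
reliability_report <- function(features_s1, features_s2, motion_pct = NULL,
                               cap_percent = 20) {
  s1 <- unique(features_s1$subject)
  s2 <- unique(features_s2$subject)
  keep <- intersect(s1, s2)
  if (length(union(s1, s2)) > length(keep)) {
    warn(sprintf("%d subject(s) present in one session only; excluded",
                 length(union(s1, s2)) - length(keep)))
  }
  if (!is.null(motion_pct)) {
    check_scalar(cap_percent, "cap_percent", lower = 0, strict_lower = TRUE)
    pass <- motion_pct |>
      group_by(.data$subject) |>
      summarise(ok = dplyr::n() == 2 && all(.data$pct_corrupted < cap_percent),
                .groups = "drop") |>
      filter(.data$ok) |> pull("subject")
    keep <- intersect(keep, pass)
  }
  if (length(keep) < 5) {
    abort(sprintf("only %d subjects pass the motion cap in both sessions",
                  length(keep)), class = "vgfc_error_validation")
  }
  long1 <- pivot_features(filter(features_s1, .data$subject %in% keep))
  long2 <- pivot_features(filter(features_s2, .data$subject %in% keep))
  both <- inner_join(long1, long2, by = c("subject", "region", "feature"),
                     suffix = c("_s1", "_s2"))
  both |>
    group_by(.data$region, .data$feature) |>
    dplyr::group_modify(function(d, key) {
      fit <- icc_absolute_agreement(cbind(d$value_s1, d$value_s2))
      tibble(icc = fit$icc, ci_lo = fit$ci95[1], ci_hi = fit$ci95[2],
             n_subjects = fit$n_subjects)
    }) |>
    ungroup()
}

#' Per-feature quartile summary of a reliability report
#'
#' The distributional view across regions (the violin-plot summary):
#' quartiles of ICC per feature.
#'
#' @param report output of [reliability_report()].
#' @return tibble (`feature`, `q25`, `median`, `q75`, `mean_icc`,
#'   `n_regions`).
#' @export
summarise_reliability <- function(report) {
  report |>
    group_by(.data$feature) |>
    summarise(q25 = stats::quantile(.data$icc, 0.25),
              median = stats::median(.data$icc),
              q75 = stats::quantile(.data$icc, 0.75),
              mean_icc = mean(.data$icc),
              n_regions = dplyr::n(),
              .groups = "drop")
}
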