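new_alert_series <- function(values, flags, sides, feature_kind, subject_id,
                             variant = "combined") {
  n <- length(flags)
  structure(
    list(values = as.numeric(values), flags = as.logical(flags),
         sides = as.character(sides), feature_kind = feature_kind,
         subject_id = subject_id, variant = variant,
         n_windows = n, n_alerts = sum(flags),
         fraction = if (n > 0L) sum(flags) / n else NA_real_),
    class = "alert_series"
  )
}

#' @export
print.alert_series <- function(x, ...) {
  cat(sprintf(
    "<alert_series> %s, subject '%s' (%s): %d/%d windows alerted (%.1f%%)\n",
    x$feature_kind, x$subject_id, x$variant, x$n_alerts, x$n_windows,
    100 * x$fraction))
  invisible(x)
}

#' Apply a learned baseline to a test feature series
#'
#' Flags each window whose feature value violates the selected side(s) of
#' the baseline thresholds. Inequalities are strict: a value above `upper`
#' is a deep/fast outlier (side `above`), a value below `lower` a
#' shallow/slow outlier (side `below`); values exactly at a threshold do
#' not alert. The canonical rules are upper-only on the moving maximum
#' ("too deep"), lower-only on the moving minimum ("too shallow"),
#' upper-only on amplitude and on dominant frequency ("too fast").
#'
#' @param features A `feature_series` of test values, non-empty.
#' @param baseline A `gaussian_baseline` or `quantile_thresholds` fit on
#'   the same feature kind.
#' @param side_rule `"two_sided"`, `"upper_only"` or `"lower_only"`.
#' @param variant Train/test variant label to carry (`"talking"`,
#'   `"not_talking"` or `"combined"`).
#' @return An `alert_series` with per-window flags, sides and the summary
#'   alert fraction.
#' @export
detect_alerts <- function(features, baseline,
                          side_rule = c("two_sided", "upper_only", "lower_only"),
                          variant = "combined") {
  stopifnot(inherits(features, "feature_series"))
  side_rule <- match.arg(side_rule)
  if (!inherits(baseline, "gaussian_baseline") &&
      !inherits(baseline, "quantile_thresholds")) {
    stop("baseline must be a gaussian_baseline or quantile_thresholds",
         call. = FALSE)
  }
  if (!identical(features$kind, baseline$feature_kind)) {
    stop(sprintf("contract error: feature kind '%s' does not match baseline kind '%s'",
                 features$kind, baseline$feature_kind), call. = FALSE)
  }
  x <- features$values
  if (length(x) == 0L) stop("contract error: empty feature series", call. = FALSE)
  above <- x > baseline$upper
  below <- x < baseline$lower
  flags <- switch(side_rule,
                  two_sided = above | below,
                  upper_only = above,
                  lower_only = below)
  sides <- rep("none", length(x))
  sides[flags & above] <- "above"
  sides[flags & below] <- "below"
  new_alert_series(x, flags, sides, features$kind, features$subject_id, variant)
}

#' Apply a bivariate frame to aligned test feature series
#'
#' Flags each window whose (x, y) point lies outside the learned
#' rectangle. No jitter is applied at test time; a point outside on both
#' axes counts once.
#'
#' @param x,y Aligned `feature_series` of test values.
#' @param frame A [fit_bivariate_frame()] result.
#' @param variant Variant label to carry.
#' @return An `alert_series`; `values` holds the x-channel feature, sides
#'   are relative to the x-axis limits (`none` for points outside on the
#'   y axis only).
#' @export
detect_bivariate_alerts <- function(x, y, frame, variant = "combined") {
  stopifnot(inherits(x, "feature_series"), inherits(y, "feature_series"),
            inherits(frame, "bivariate_frame"))
  if (length(x$values) != length(y$values)) {
    stop("alignment error: feature series differ in length", call. = FALSE)
  }
  flags <- frame_outside(x$values, y$values,
                         c(frame$x_lower, frame$x_upper),
                         c(frame$y_lower, frame$y_upper))
  sides <- rep("none", length(flags))
  sides[flags & x$values > frame$x_upper] <- "above"
  sides[flags & x$values < frame$x_lower] <- "below"
  new_alert_series(x$values, flags, sides, paste0(x$kind, "+", y$kind),
                   x$subject_id, variant)
}

#' Fraction of windows alerted
#'
#' @param alerts An `alert_series` with at least one window.
#' @return `n_alerts / n_windows`.
#' @export
alert_fraction <- function(alerts) {
  stopifnot(inherits(alerts, "alert_series"))
  if (alerts$n_windows == 0L) {
    stop("contract error: empty alert series", call. = FALSE)
  }
  alerts$n_alerts / alerts$n_windows
}

#' Count alerts right and left of the training mean
#'
#' RA counts alerted windows whose feature value lies strictly above the
#' baseline mean, LA those strictly below; values exactly at the mean
#' count toward neither. Under an upward shift at test time (e.g. running
#' vs a resting baseline), RA > LA is the expected signature.
#'
#' @param features The test `feature_series` the alerts were computed on.
#' @param alerts The matching `alert_series`.
#' @param baseline The `gaussian_baseline` supplying the training mean.
#' @return An object of class `ra_la_counts` with fields `ra`, `la`,
#'   `window_size`.
#' @export
ra_la_counts <- function(features, alerts, baseline) {
  stopifnot(inherits(features, "feature_series"),
            inherits(alerts, "alert_series"),
            inherits(baseline, "gaussian_baseline"))
  if (length(features$values) != alerts$n_windows) {
    stop("alignment error: features and alerts differ in length", call. = FALSE)
  }
  v <- features$values[alerts$flags]
  structure(
    list(ra = sum(v > baseline$mu), la = sum(v < baseline$mu),
         window_size = features$window$size,
         n_alerts = alerts$n_alerts, subject_id = features$subject_id),
    class = "ra_la_counts"
  )
}

#' @export
print.ra_la_counts <- function(x, ...) {
  cat(sprintf("<ra_la_counts> subject '%s', W=%d: RA=%d LA=%d (of %d alerts)\n",
              x$subject_id, x$window_size, x$ra, x$la, x$n_alerts))
  invisible(x)
}

#' Cohort summary of per-subject alert fractions
#'
#' Groups a collection of per-subject alert series by variant and feature
#' kind and reports the mean and standard deviation (sample convention;
#' 0 for a single subject) of the per-subject alert fractions — the
#' study's primary evaluation statistic.
#'
#' @param per_subject_alerts Non-empty list of `alert_series`.
#' @return A data frame with one row per (variant, feature_kind):
#'   `variant`, `feature_kind`, `n_subjects`, `mean_fraction`,
#'   `sd_fraction`.
#' @export
cohort_summary <- function(per_subject_alerts) {
  if (length(per_subject_alerts) == 0L) {
    stop("contract error: empty collection", call. = FALSE)
  }
  ok <- vapply(per_subject_alerts, inherits, logical(1), "alert_series")
  if (!all(ok)) stop("all elements must be alert_series objects", call. = FALSE)
  df <- data.frame(
    variant = vapply(per_subject_alerts, `[[`, character(1), "variant"),
    feature_kind = vapply(per_subject_alerts, `[[`, character(1), "feature_kind"),
    subject_id = vapply(per_subject_alerts, `[[`, character(1), "subject_id"),
    fraction = vapply(per_subject_alerts, `[[`, numeric(1), "fraction")
  )
  groups <- split(df, list(df$variant, df$feature_kind), drop = TRUE)
  out <- do.call(rbind, lapply(groups, function(g) {
    if (anyDuplicated(g$subject_id)) {
      stop("contract error: duplicate subject within a (variant, feature) group",
           call. = FALSE)
    }
    data.frame(
      variant = g$variant[1L], feature_kind = g$feature_kind[1L],
      n_subjects = nrow(g),
      mean_fraction = mean(g$fraction),
      sd_fraction = if (nrow(g) > 1L) stats::sd(g$fraction) else 0
    )
  }))
  rownames(out) <- NULL
  out
}
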