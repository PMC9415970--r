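#' Construct a respiration-belt trace
#'
#' A `respiration_trace` holds a single-channel belt-extension signal
#' \eqn{s(i)} sampled at a fixed rate, optionally annotated per sample with
#' the activity being performed (`sitting`, `walking`, `running`, `other`)
#' and a talking flag. Belt extension is in arbitrary units; the field
#' protocol this package targets samples at 12 Hz.
#'
#' @param samples Numeric vector of belt-extension values, non-empty.
#' @param sampling_rate Sampling rate in Hz, > 0.
#' @param activity Optional character vector, one label per sample, each in
#'   `c("sitting", "walking", "running", "other")`.
#' @param talking Optional logical vector, one flag per sample.
#' @param subject_id Opaque subject identifier.
#' @return An object of class `respiration_trace`.
#' @export
#' @examples
#' tr <- respiration_trace(sin(2 * pi * 0.25 * (0:119) / 12), sampling_rate = 12)
#' length(tr$samples)
respiration_trace <- function(samples, sampling_rate, activity = NULL,
                              talking = NULL, subject_id = "anonymous") {
  samples <- as.numeric(samples)
  if (length(samples) == 0L) {
    stop("`samples` must be non-empty", call. = FALSE)
  }
  if (anyNA(samples)) {
    stop("`samples` must not contain missing values", call. = FALSE)
  }
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      !is.finite(sampling_rate) || sampling_rate <= 0) {
    stop("`sampling_rate` must be a single positive number (Hz)", call. = FALSE)
  }
  if (!is.null(activity)) {
    activity <- as.character(activity)
    if (length(activity) != length(samples)) {
      stop("`activity` must have one label per sample", call. = FALSE)
    }
    bad <- setdiff(unique(activity), c("sitting", "walking", "running", "other"))
    if (length(bad) > 0L) {
      stop("unknown activity label(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
  }
  if (!is.null(talking)) {
    talking <- as.logical(talking)
    if (length(talking) != length(samples) || anyNA(talking)) {
      stop("`talking` must be one non-missing flag per sample", call. = FALSE)
    }
  }
  structure(
    list(samples = samples, sampling_rate = sampling_rate,
         activity = activity, talking = talking,
         subject_id = as.character(subject_id)),
    class = "respiration_trace"
  )
}

#' @export
print.respiration_trace <- function(x, ...) {
  cat(sprintf("<respiration_trace> subject '%s': %d samples at %g Hz (%.1f s)\n",
              x$subject_id, length(x$samples), x$sampling_rate,
              length(x$samples) / x$sampling_rate))
  if (!is.null(x$activity)) {
    tab <- table(x$activity)
    cat("  activity: ", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
        "\n", sep = "")
  }
  if (!is.null(x$talking)) {
    cat(sprintf("  talking samples: %d\n", sum(x$talking)))
  }
  invisible(x)
}

#' Subset a trace by sample index
#'
#' Keeps the sampling rate and subject id and subsets samples and any
#' per-sample labels together, so the invariant that labels align with
#' samples cannot be broken.
#'
#' @param trace A [respiration_trace()].
#' @param idx Integer or logical index into the samples.
#' @return A `respiration_trace` over the selected samples.
#' @export
trace_slice <- function(trace, idx) {
  stopifnot(inherits(trace, "respiration_trace"))
  respiration_trace(
    samples = trace$samples[idx],
    sampling_rate = trace$sampling_rate,
    activity = if (!is.null(trace$activity)) trace$activity[idx],
    talking = if (!is.null(trace$talking)) trace$talking[idx],
    subject_id = trace$subject_id
  )
}

#' Pair two synchronous channels
#'
#' Bundles a respiration channel with a second physiological channel
#' (e.g. ocular movement in the 63-s, 128-Hz two-channel setting) recorded
#' at the same rate and length.
#'
#' @param channel_a A [respiration_trace()] (respiration).
#' @param channel_b A [respiration_trace()] (second channel).
#' @return An object of class `bivariate_trace`.
#' @export
bivariate_trace <- function(channel_a, channel_b) {
  stopifnot(inherits(channel_a, "respiration_trace"),
            inherits(channel_b, "respiration_trace"))
  if (length(channel_a$samples) != length(channel_b$samples)) {
    stop("channels must have equal sample counts", call. = FALSE)
  }
  if (channel_a$sampling_rate != channel_b$sampling_rate) {
    stop("channels must share a sampling rate", call. = FALSE)
  }
  structure(list(channel_a = channel_a, channel_b = channel_b),
            class = "bivariate_trace")
}

#' Read a respiration trace from CSV
#'
#' Expects a header row and one sample per data row. The sample column is
#' required; `activity` and `talking` columns are attached as labels when
#' present under the mapped names.
#'
#' @param path Path to a CSV file.
#' @param sampling_rate Sampling rate in Hz (supplied out-of-band; the files
#'   carry samples only, no timestamps).
#' @param column_map Named character vector mapping the fields `sample`,
#'   `activity`, `talking` to column names in the file.
#' @param subject_id Subject identifier to attach.
#' @return A [respiration_trace()].
#' @export
read_trace_csv <- function(path, sampling_rate,
                           column_map = c(sample = "sample",
                                          activity = "activity",
                                          talking = "talking"),
                           subject_id = "anonymous") {
  if (!file.exists(path)) {
    stop("trace file not found: ", path, call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  sample_col <- column_map[["sample"]]
  if (!sample_col %in% names(df)) {
    stop(sprintf("format error: sample column '%s' missing from %s",
                 sample_col, path), call. = FALSE)
  }
  raw <- df[[sample_col]]
  samples <- suppressWarnings(as.numeric(raw))
  bad <- which(is.na(samples) & !is.na(raw) & trimws(as.character(raw)) != "")
  if (length(bad) > 0L) {
    stop(sprintf("parse error: non-numeric sample value '%s' at data row %d",
                 as.character(raw[bad[1L]]), bad[1L]), call. = FALSE)
  }
  if (anyNA(samples)) {
    stop(sprintf("parse error: empty sample value at data row %d",
                 which(is.na(samples))[1L]), call. = FALSE)
  }
  activity <- NULL
  talking <- NULL
  act_col <- if ("activity" %in% names(column_map)) column_map[["activity"]]
  if (!is.null(act_col) && act_col %in% names(df)) activity <- df[[act_col]]
  talk_col <- if ("talking" %in% names(column_map)) column_map[["talking"]]
  if (!is.null(talk_col) && talk_col %in% names(df)) {
    tv <- df[[talk_col]]
    talking <- if (is.character(tv)) toupper(trimws(tv)) %in% c("TRUE", "T", "1")
               else as.logical(tv)
  }
  respiration_trace(samples, sampling_rate, activity = activity,
                    talking = talking, subject_id = subject_id)
}

#' Write a respiration trace to CSV
#'
#' One sample per row with a header; label columns are written only when
#' present on the trace. `read_trace_csv()` on the result reproduces the
#' samples and labels.
#'
#' @param trace A [respiration_trace()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "respiration_trace"))
  df <- data.frame(sample = trace$samples)
  if (!is.null(trace$activity)) df$activity <- trace$activity
  if (!is.null(trace$talking)) df$talking <- trace$talking
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write an alert series to CSV
#'
#' One row per window: window index (0-based, matching the feature series),
#' feature value, alert flag, side of the baseline mean. An empty series
#' yields a header-only file.
#'
#' @param alerts An `alert_series` (see [detect_alerts()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alerts_csv <- function(alerts, path) {
  stopifnot(inherits(alerts, "alert_series"))
  df <- data.frame(
    window = seq_along(alerts$flags) - 1L,
    value = alerts$values,
    alert = alerts$flags,
    side = alerts$sides
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read an alert table written by [write_alerts_csv()]
#'
#' @param path Path to an alert CSV.
#' @return A data frame with columns `window`, `value`, `alert`, `side`.
#' @export
read_alerts_csv <- function(path) {
  if (!file.exists(path)) {
    stop("alert file not found: ", path, call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(window = "integer", value = "numeric",
                                       alert = "logical", side = "character"))
  df
}
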