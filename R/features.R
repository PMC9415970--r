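#' Sliding-window specification
#'
#' Windows of `size` consecutive samples taken every `stride` samples.
#' Two enumeration conventions are supported because the two feature
#' families index their windows differently: `all_full_windows` yields
#' `floor((N - size)/stride) + 1` windows for a trace of length `N`
#' (start indices 0 … N - size at stride 1), while `drop_last` omits the
#' final full window, yielding `floor((N - size)/stride)` (start indices
#' 0 … N - size - 1). Extrema and amplitude default to the former,
#' dominant frequency to the latter.
#'
#' @param size Window length in samples, >= 1.
#' @param stride Hop between window starts in samples, >= 1. Default 1
#'   (fully overlapping sliding windows).
#' @param enumeration `"all_full_windows"` or `"drop_last"`.
#' @return An object of class `window_spec`.
#' @export
window_spec <- function(size, stride = 1L,
                        enumeration = c("all_full_windows", "drop_last")) {
  enumeration <- match.arg(enumeration)
  size <- as.integer(size)
  stride <- as.integer(stride)
  if (is.na(size) || size < 1L) stop("`size` must be a positive integer", call. = FALSE)
  if (is.na(stride) || stride < 1L) stop("`stride` must be a positive integer", call. = FALSE)
  structure(list(size = size, stride = stride, enumeration = enumeration),
            class = "window_spec")
}

#' Number of windows a spec yields on a trace of length n
#'
#' @param spec A [window_spec()].
#' @param n Trace length in samples.
#' @return Integer window count.
#' @export
n_windows <- function(spec, n) {
  stopifnot(inherits(spec, "window_spec"))
  n <- as.integer(n)
  if (n < spec$size) {
    stop(sprintf("trace of length %d is shorter than window size %d",
                 n, spec$size), call. = FALSE)
  }
  full <- (n - spec$size) %/% spec$stride + 1L
  switch(spec$enumeration,
         all_full_windows = full,
         drop_last = full - 1L)
}

new_feature_series <- function(kind, values, window, subject_id, sampling_rate) {
  structure(list(kind = kind, values = as.numeric(values), window = window,
                 subject_id = subject_id, sampling_rate = sampling_rate),
            class = "feature_series")
}

#' @export
print.feature_series <- function(x, ...) {
  cat(sprintf("<feature_series> %s: %d windows (W=%d, stride=%d, %s), subject '%s'\n",
              x$kind, length(x$values), x$window$size, x$window$stride,
              x$window$enumeration, x$subject_id))
  invisible(x)
}

window_starts <- function(spec, n) {
  k <- n_windows(spec, n)
  if (k == 0L) integer(0) else seq.int(1L, by = spec$stride, length.out = k)
}

#' Moving maximum or minimum of a trace
#'
#' For each window starting at sample index i, keeps the extreme of
#' s(i) … s(i+W-1). The moving maximum tracks the deepest inhalation in
#' the window (largest belt extension), the moving minimum the fullest
#' exhalation.
#'
#' @param trace A [respiration_trace()].
#' @param window A [window_spec()]. Default: size 12, stride 1,
#'   `all_full_windows` — one-second windows at the 12-Hz field rate.
#' @param which `"max"` or `"min"`.
#' @return A `feature_series` of kind `moving_max` or `moving_min`.
#' @export
#' @examples
#' tr <- respiration_trace(sin(2 * pi * (0:99) / 20), sampling_rate = 12)
#' m <- moving_extremum(tr, window_spec(12), "max")
#' length(m$values)  # 100 - 12 + 1
moving_extremum <- function(trace, window = window_spec(12L), which = c("max", "min")) {
  stopifnot(inherits(trace, "respiration_trace"))
  which <- match.arg(which)
  n <- length(trace$samples)
  k <- n_windows(window, n)
  fun <- if (which == "max") max else min
  vals <- zoo::rollapply(trace$samples, width = window$size, by = window$stride,
                         FUN = fun, align = "left", partial = FALSE)
  new_feature_series(
    kind = paste0("moving_", which),
    values = vals[seq_len(k)],
    window = window,
    subject_id = trace$subject_id,
    sampling_rate = trace$sampling_rate
  )
}

#' Per-window breathing amplitude
#'
#' Subtracts the moving minimum from the moving maximum window by window:
#' A(i) = M(i) - m(i), a proxy for breath depth. Both inputs must come
#' from the same trace with the same window spec.
#'
#' @param max_series `feature_series` of kind `moving_max`.
#' @param min_series `feature_series` of kind `moving_min`.
#' @return A `feature_series` of kind `amplitude`; all values >= 0.
#' @export
amplitude <- function(max_series, min_series) {
  stopifnot(inherits(max_series, "feature_series"),
            inherits(min_series, "feature_series"))
  if (max_series$kind != "moving_max" || min_series$kind != "moving_min") {
    stop("inputs must be a moving_max and a moving_min series", call. = FALSE)
  }
  if (!identical(unclass(max_series$window), unclass(min_series$window)) ||
      length(max_series$values) != length(min_series$values)) {
    stop("alignment error: series differ in window spec or length", call. = FALSE)
  }
  if (!identical(max_series$subject_id, min_series$subject_id)) {
    stop("alignment error: series come from different subjects", call. = FALSE)
  }
  new_feature_series(
    kind = "amplitude",
    values = max_series$values - min_series$values,
    window = max_series$window,
    subject_id = max_series$subject_id,
    sampling_rate = max_series$sampling_rate
  )
}

#' Dominant-frequency bin per window
#'
#' For each window w_i, returns the index j maximising |DFT(w_i)_j| — the
#' frequency bin carrying the most energy, a proxy for breathing rate
#' (bin j corresponds to j * rate / W Hz). Ties break to the smallest bin.
#'
#' Two modes: the default demeans each window and searches bins
#' 1 … floor(W/2) (a non-zero-mean belt signal otherwise makes the DC bin
#' trivially dominant); `demean = FALSE, bin_range = "all_bins"` searches
#' all W bins of the raw window, including DC and the mirrored upper half.
#'
#' @param trace A [respiration_trace()].
#' @param window A [window_spec()]; default size 48, stride 1, `drop_last`.
#' @param demean Subtract the window mean before the DFT? Default `TRUE`.
#' @param bin_range `"positive_bins"` (1 … floor(W/2)) or `"all_bins"`
#'   (0 … W-1).
#' @return A `feature_series` of kind `dominant_frequency`; values are
#'   integer bin indices in `[0, W-1]`.
#' @export
dominant_frequency <- function(trace,
                               window = window_spec(48L, enumeration = "drop_last"),
                               demean = TRUE,
                               bin_range = c("positive_bins", "all_bins")) {
  stopifnot(inherits(trace, "respiration_trace"))
  bin_range <- match.arg(bin_range)
  if (window$size < 2L) stop("window size must be at least 2", call. = FALSE)
  n <- length(trace$samples)
  starts <- window_starts(window, n)
  W <- window$size
  half <- W %/% 2L
  vals <- vapply(starts, function(s) {
    w <- trace$samples[s:(s + W - 1L)]
    if (demean) w <- w - mean(w)
    mag <- Mod(stats::fft(w))
    if (bin_range == "positive_bins") {
      # bins 1..floor(W/2); mag index j+1 for bin j
      which.max(mag[2L:(half + 1L)])          # ties: smallest bin
    } else {
      which.max(mag) - 1L
    }
  }, numeric(1))
  new_feature_series(
    kind = "dominant_frequency",
    values = vals,
    window = window,
    subject_id = trace$subject_id,
    sampling_rate = trace$sampling_rate
  )
}
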