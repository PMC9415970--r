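#' Canonical alert side for a feature kind
#'
#' Deep-breath detection looks above the baseline on the moving maximum,
#' shallow-breath detection below it on the moving minimum; amplitude and
#' dominant frequency alert above only (breathing too deep / too fast).
#'
#' @param kind Feature kind string.
#' @return `"upper_only"` or `"lower_only"`.
#' @export
feature_side_rule <- function(kind) {
  switch(kind,
         moving_max = "upper_only",
         moving_min = "lower_only",
         amplitude = "upper_only",
         dominant_frequency = "upper_only",
         stop("unknown feature kind: ", kind, call. = FALSE))
}

extract_feature <- function(trace, kind, w_ext, w_fft, stride = 1L,
                            fft_mode = "demeaned") {
  ext_spec <- window_spec(w_ext, stride, "all_full_windows")
  switch(kind,
    moving_max = moving_extremum(trace, ext_spec, "max"),
    moving_min = moving_extremum(trace, ext_spec, "min"),
    amplitude = amplitude(moving_extremum(trace, ext_spec, "max"),
                          moving_extremum(trace, ext_spec, "min")),
    dominant_frequency = {
      fft_spec <- window_spec(w_fft, stride, "drop_last")
      if (fft_mode == "paper_literal") {
        dominant_frequency(trace, fft_spec, demean = FALSE, bin_range = "all_bins")
      } else {
        dominant_frequency(trace, fft_spec, demean = TRUE,
                           bin_range = "positive_bins")
      }
    },
    stop("unknown feature kind: ", kind, call. = FALSE))
}

fit_feature_baseline <- function(train_features, kind, alpha, outlier_fraction,
                                 freq_rule = c("quantile", "gaussian"),
                                 jitter_seed = 1L) {
  freq_rule <- match.arg(freq_rule)
  if (kind == "dominant_frequency" && freq_rule == "quantile") {
    fit_quantile_thresholds(train_features, outlier_fraction,
                            sidedness = feature_side_rule(kind),
                            jitter_seed = jitter_seed)
  } else {
    fit_gaussian_baseline(train_features, alpha)
  }
}

#' Train baselines and detect alerts for one subject
#'
#' Runs the full per-person pipeline on one labelled trace: split into
#' training (rest) and test segments, filter by talking variant, extract
#' each feature, learn its baseline on the training segment, and apply it
#' to the test segment with the feature's canonical side rule.
#'
#' @param trace A labelled [respiration_trace()].
#' @param mode `"field"` (train on pre-run sitting+walking, test on
#'   running) or `"literature"` (first half vs second half).
#' @param variant `"combined"`, `"talking"` or `"not_talking"`.
#' @param features Character vector of feature kinds to run.
#' @param w_ext Extremum/amplitude window size (samples). Defaults: 12
#'   in field mode, 128 in literature mode.
#' @param w_fft FFT window size (samples). Defaults: 48 field, 128
#'   literature.
#' @param stride Window stride; default 1.
#' @param alpha Gaussian-baseline width in standard deviations; default 1.5.
#' @param outlier_fraction Quantile-threshold training-outlier fraction;
#'   default 0.05.
#' @param fft_mode `"demeaned"` or `"paper_literal"`.
#' @param freq_rule Baseline family for dominant frequency:
#'   `"quantile"` (default) or `"gaussian"`.
#' @param jitter_seed Seed for quantile-threshold jitter.
#' @return Named list per feature kind, each with `train_features`,
#'   `test_features`, `baseline` and `alerts`.
#' @export
analyze_subject <- function(trace, mode = c("field", "literature"),
                            variant = "combined",
                            features = c("moving_max", "moving_min",
                                         "amplitude", "dominant_frequency"),
                            w_ext = NULL, w_fft = NULL, stride = 1L,
                            alpha = 1.5, outlier_fraction = 0.05,
                            fft_mode = "demeaned",
                            freq_rule = "quantile", jitter_seed = 1L) {
  mode <- match.arg(mode)
  if (is.null(w_ext)) w_ext <- if (mode == "field") 12L else 128L
  if (is.null(w_fft)) w_fft <- if (mode == "field") 48L else 128L
  sp <- training_split(trace, mode)
  train <- variant_filter(sp$train, variant)
  test <- variant_filter(sp$test, variant)
  out <- lapply(features, function(kind) {
    tr_f <- extract_feature(train, kind, w_ext, w_fft, stride, fft_mode)
    te_f <- extract_feature(test, kind, w_ext, w_fft, stride, fft_mode)
    bl <- fit_feature_baseline(tr_f, kind, alpha, outlier_fraction,
                               freq_rule, jitter_seed)
    al <- detect_alerts(te_f, bl, side_rule = feature_side_rule(kind),
                        variant = variant)
    list(train_features = tr_f, test_features = te_f,
         baseline = bl, alerts = al)
  })
  stats::setNames(out, features)
}

#' RA/LA window-size sensitivity sweep
#'
#' For each candidate extremum window size, refits the amplitude baseline
#' per subject and counts two-sided amplitude alerts right (RA) and left
#' (LA) of the training mean on the test segment, then tallies how many
#' subjects show RA > LA — the expected signature when test breathing is
#' deeper than the baseline.
#'
#' @param traces List of labelled [respiration_trace()] objects.
#' @param window_sizes Integer vector of window sizes to sweep.
#' @param mode,variant,alpha,stride As in [analyze_subject()].
#' @return Data frame: `window_size`, `n_subjects`, `n_ra_gt_la`, plus a
#'   `per_subject` attribute with the raw RA/LA counts.
#' @export
ra_la_sweep <- function(traces, window_sizes = c(2, 3, 4, 12, 19, 20, 40),
                        mode = "field", variant = "combined",
                        alpha = 1.5, stride = 1L) {
  stopifnot(length(traces) > 0)
  rows <- lapply(window_sizes, function(W) {
    counts <- lapply(traces, function(trace) {
      sp <- training_split(trace, mode)
      train <- variant_filter(sp$train, variant)
      test <- variant_filter(sp$test, variant)
      spec <- window_spec(W, stride, "all_full_windows")
      amp_of <- function(tr) amplitude(moving_extremum(tr, spec, "max"),
                                       moving_extremum(tr, spec, "min"))
      tr_f <- amp_of(train)
      te_f <- amp_of(test)
      bl <- fit_gaussian_baseline(tr_f, alpha)
      al <- detect_alerts(te_f, bl, side_rule = "two_sided", variant = variant)
      ra_la_counts(te_f, al, bl)
    })
    ra <- vapply(counts, `[[`, numeric(1), "ra")
    la <- vapply(counts, `[[`, numeric(1), "la")
    data.frame(window_size = W, n_subjects = length(traces),
               n_ra_gt_la = sum(ra > la))
  })
  do.call(rbind, rows)
}

#' Fit and apply the bivariate outlier frame for one subject
#'
#' Literature-mode two-channel analysis: dominant-frequency features are
#' extracted from both channels, the frame is learned on the training
#' half (with jitter) and applied to the test half.
#'
#' @param bt A [bivariate_trace()].
#' @param w_fft FFT window size; default 128.
#' @param joint_outlier_fraction Target training outside-fraction;
#'   default 0.05.
#' @param jitter_seed,jitter_halfwidth Frame jitter parameters.
#' @param fft_mode `"demeaned"` or `"paper_literal"`.
#' @return List with `frame`, `alerts` (on the test half),
#'   `train_features` and `test_features` (x/y pairs).
#' @export
analyze_bivariate <- function(bt, w_fft = 128L, joint_outlier_fraction = 0.05,
                              jitter_seed = 1L, jitter_halfwidth = 0.5,
                              fft_mode = "demeaned") {
  stopifnot(inherits(bt, "bivariate_trace"))
  sp_a <- training_split(bt$channel_a, "literature")
  sp_b <- training_split(bt$channel_b, "literature")
  feat <- function(tr) extract_feature(tr, "dominant_frequency",
                                       w_ext = w_fft, w_fft = w_fft,
                                       fft_mode = fft_mode)
  tr_x <- feat(sp_a$train); tr_y <- feat(sp_b$train)
  te_x <- feat(sp_a$test);  te_y <- feat(sp_b$test)
  frame <- fit_bivariate_frame(tr_x, tr_y, joint_outlier_fraction,
                               jitter_seed, jitter_halfwidth)
  alerts <- detect_bivariate_alerts(te_x, te_y, frame)
  list(frame = frame, alerts = alerts,
       train_features = list(x = tr_x, y = tr_y),
       test_features = list(x = te_x, y = te_y))
}
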