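#' Fit a per-person Gaussian baseline
#'
#' Summarises a training feature series by its mean and standard deviation
#' and derives symmetric outlier thresholds mu +/- alpha * sigma. A window
#' whose feature value exceeds `upper` is a deep-breath (or fast-breathing)
#' outlier; one below `lower` is a shallow (or slow) outlier. `sigma = 0`
#' (a constant training signal) is legal: the baseline degenerates and any
#' deviation from `mu` alerts.
#'
#' @param features A `feature_series` of training values, non-empty.
#' @param alpha Number of standard deviations defining an outlier, > 0.
#'   Default 1.5.
#' @param ddof Degrees-of-freedom correction for the standard deviation:
#'   0 (population convention, default) or 1 (sample convention).
#' @return An object of class `gaussian_baseline` with fields `mu`,
#'   `sigma`, `alpha`, `lower`, `upper`, `feature_kind`, `subject_id`.
#' @export
#' @examples
#' fs <- structure(list(kind = "amplitude", values = rnorm(100, 5),
#'                      window = window_spec(12), subject_id = "s1",
#'                      sampling_rate = 12), class = "feature_series")
#' b <- fit_gaussian_baseline(fs, alpha = 1.5)
#' b$upper - b$mu == 1.5 * b$sigma
fit_gaussian_baseline <- function(features, alpha = 1.5, ddof = 0L) {
  stopifnot(inherits(features, "feature_series"))
  x <- features$values
  if (length(x) == 0L) stop("fit error: empty feature series", call. = FALSE)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0) {
    stop("`alpha` must be a single positive number", call. = FALSE)
  }
  if (!ddof %in% c(0L, 1L)) stop("`ddof` must be 0 or 1", call. = FALSE)
  n <- length(x)
  mu <- mean(x)
  ss <- sum((x - mu)^2)
  sigma <- if (n - ddof > 0L) sqrt(ss / (n - ddof)) else 0
  structure(
    list(mu = mu, sigma = sigma, alpha = alpha,
         lower = mu - alpha * sigma, upper = mu + alpha * sigma,
         n_train = n, ddof = as.integer(ddof),
         feature_kind = features$kind, subject_id = features$subject_id,
         window = features$window),
    class = "gaussian_baseline"
  )
}

#' @export
print.gaussian_baseline <- function(x, ...) {
  cat(sprintf(
    "<gaussian_baseline> %s, subject '%s': mu=%.4g sigma=%.4g alpha=%g -> [%.4g, %.4g]\n",
    x$feature_kind, x$subject_id, x$mu, x$sigma, x$alpha, x$lower, x$upper))
  invisible(x)
}

# Deterministic per-purpose RNG stream: runs `expr` under a local seed
# without disturbing the caller's RNG state.
with_local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
              rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

apply_jitter <- function(x, seed, halfwidth = 0.5) {
  if (is.null(seed)) return(x)
  with_local_seed(seed, x + stats::runif(length(x), -halfwidth, halfwidth))
}

#' Fit empirical quantile outlier thresholds
#'
#' Thresholds are empirical quantiles (linear interpolation between order
#' statistics, `stats::quantile` type 7) of the training values, so that a
#' requested fraction of the training data itself falls outside them. A
#' two-sided fit splits the fraction equally between the tails; one-sided
#' fits put the whole fraction in one tail and leave the other threshold
#' at infinity. Integer-valued features (dominant-frequency bins) can tie
#' heavily at one value, making raw quantiles degenerate; an optional
#' uniform jitter on +/- `jitter_halfwidth` (half the bin spacing by
#' default) is applied before the quantiles to break ties.
#'
#' @param features A `feature_series`, non-empty.
#' @param outlier_fraction Target fraction of training values outside the
#'   thresholds, in (0, 1). Default 0.05.
#' @param sidedness `"two_sided"`, `"upper_only"` or `"lower_only"`.
#' @param jitter_seed Integer seed for the tie-breaking jitter, or `NULL`
#'   for no jitter.
#' @param jitter_halfwidth Half-width of the uniform jitter. Default 0.5.
#' @return An object of class `quantile_thresholds`.
#' @export
fit_quantile_thresholds <- function(features, outlier_fraction = 0.05,
                                    sidedness = c("two_sided", "upper_only",
                                                  "lower_only"),
                                    jitter_seed = NULL,
                                    jitter_halfwidth = 0.5) {
  stopifnot(inherits(features, "feature_series"))
  sidedness <- match.arg(sidedness)
  x <- features$values
  if (length(x) == 0L) stop("fit error: empty feature series", call. = FALSE)
  if (!is.numeric(outlier_fraction) || length(outlier_fraction) != 1L ||
      outlier_fraction <= 0 || outlier_fraction >= 1) {
    stop("parameter error: `outlier_fraction` must lie in (0, 1)", call. = FALSE)
  }
  xj <- apply_jitter(x, jitter_seed, jitter_halfwidth)
  q <- function(p) unname(stats::quantile(xj, p, type = 7, names = FALSE))
  thr <- switch(sidedness,
    two_sided = c(lower = q(outlier_fraction / 2),
                  upper = q(1 - outlier_fraction / 2)),
    upper_only = c(lower = -Inf, upper = q(1 - outlier_fraction)),
    lower_only = c(lower = q(outlier_fraction), upper = Inf)
  )
  structure(
    list(lower = thr[["lower"]], upper = thr[["upper"]],
         outlier_fraction = outlier_fraction, sidedness = sidedness,
         jitter_seed = jitter_seed, jitter_halfwidth = jitter_halfwidth,
         n_train = length(x),
         feature_kind = features$kind, subject_id = features$subject_id,
         window = features$window),
    class = "quantile_thresholds"
  )
}

#' @export
print.quantile_thresholds <- function(x, ...) {
  cat(sprintf(
    "<quantile_thresholds> %s, subject '%s': %s %.3g -> [%.4g, %.4g]\n",
    x$feature_kind, x$subject_id, x$sidedness, x$outlier_fraction,
    x$lower, x$upper))
  invisible(x)
}

frame_outside <- function(x, y, xlim, ylim) {
  x < xlim[1L] | x > xlim[2L] | y < ylim[1L] | y > ylim[2L]
}

#' Fit a bivariate rectangular outlier frame
#'
#' Learns an axis-aligned rectangle over two feature series (respiration
#' and a second channel) such that a stated fraction of the training
#' points fall outside it — the "extreme 5%" by default. Uniform jitter
#' is first added to both coordinates (integer-valued dominant-frequency
#' features are otherwise too discrete to threshold). Per-axis thresholds
#' are symmetric two-sided quantiles at a common tail level; because the
#' joint outside-fraction of a rectangle is not simply the sum of the
#' marginal tails, the tail level is calibrated numerically (bisection)
#' until the jittered training points outside the rectangle match the
#' requested joint fraction to within 1/n.
#'
#' @param x,y `feature_series` of equal length (x: respiration feature,
#'   y: second-channel feature).
#' @param joint_outlier_fraction Target fraction of training points
#'   outside the rectangle, in (0, 1). Default 0.05.
#' @param jitter_seed Integer seed for the jitter. Default 1.
#' @param jitter_halfwidth Half-width of the uniform jitter. Default 0.5.
#' @return An object of class `bivariate_frame` with per-axis
#'   `quantile_thresholds`-style limits and the calibrated tail level.
#' @export
fit_bivariate_frame <- function(x, y, joint_outlier_fraction = 0.05,
                                jitter_seed = 1L, jitter_halfwidth = 0.5) {
  stopifnot(inherits(x, "feature_series"), inherits(y, "feature_series"))
  if (length(x$values) != length(y$values)) {
    stop("alignment error: feature series differ in length", call. = FALSE)
  }
  n <- length(x$values)
  if (n == 0L) stop("fit error: empty feature series", call. = FALSE)
  p <- joint_outlier_fraction
  if (!is.numeric(p) || length(p) != 1L || p <= 0 || p >= 1) {
    stop("parameter error: `joint_outlier_fraction` must lie in (0, 1)",
         call. = FALSE)
  }
  jit <- with_local_seed(jitter_seed, list(
    x = x$values + stats::runif(n, -jitter_halfwidth, jitter_halfwidth),
    y = y$values + stats::runif(n, -jitter_halfwidth, jitter_halfwidth)
  ))
  limits_at <- function(t) {
    # symmetric two-sided per-axis quantiles at tail level t
    list(
      xlim = unname(stats::quantile(jit$x, c(t / 2, 1 - t / 2), type = 7)),
      ylim = unname(stats::quantile(jit$y, c(t / 2, 1 - t / 2), type = 7))
    )
  }
  outside_frac <- function(t) {
    lm <- limits_at(t)
    mean(frame_outside(jit$x, jit$y, lm$xlim, lm$ylim))
  }
  # outside_frac is nondecreasing in t; bisect on t in (0, p]
  lo <- 0
  hi <- p
  # ensure the bracket: at t = p the per-axis tails alone give >= p unless
  # outliers coincide on both axes; widen if needed
  while (outside_frac(hi) < p && hi < 1 - 1e-9) hi <- min(1 - 1e-9, hi * 2)
  for (iter in seq_len(60L)) {
    mid <- (lo + hi) / 2
    if (outside_frac(mid) < p) lo <- mid else hi <- mid
  }
  t_star <- hi
  achieved <- outside_frac(t_star)
  # pick whichever bracket end lands closer to the target
  if (abs(outside_frac(lo) - p) < abs(achieved - p)) {
    t_star <- lo
    achieved <- outside_frac(lo)
  }
  lm <- limits_at(t_star)
  structure(
    list(x_lower = lm$xlim[1L], x_upper = lm$xlim[2L],
         y_lower = lm$ylim[1L], y_upper = lm$ylim[2L],
         joint_outlier_fraction = p, per_axis_tail_level = t_star,
         training_outside_fraction = achieved,
         jitter_seed = jitter_seed, jitter_halfwidth = jitter_halfwidth,
         n_train = n,
         x_kind = x$kind, y_kind = y$kind, subject_id = x$subject_id),
    class = "bivariate_frame"
  )
}

#' @export
print.bivariate_frame <- function(x, ...) {
  cat(sprintf(
    "<bivariate_frame> subject '%s': x[%.4g, %.4g] * y[%.4g, %.4g], target %.3g, training outside %.4g\n",
    x$subject_id, x$x_lower, x$x_upper, x$y_lower, x$y_upper,
    x$joint_outlier_fraction, x$training_outside_fraction))
  invisible(x)
}

#' Serialize a baseline to JSON
#'
#' Writes all fields needed to re-apply the baseline to new data, so that
#' training and detection can run as separate invocations.
#'
#' @param baseline A `gaussian_baseline`, `quantile_thresholds` or
#'   `bivariate_frame`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_baseline_json <- function(baseline, path) {
  cls <- class(baseline)[1L]
  if (!cls %in% c("gaussian_baseline", "quantile_thresholds", "bivariate_frame")) {
    stop("not a baseline object", call. = FALSE)
  }
  obj <- unclass(baseline)
  obj$baseline_class <- cls
  if (!is.null(obj$window)) obj$window <- unclass(obj$window)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a baseline written by [write_baseline_json()]
#'
#' @param path Path to a baseline JSON file.
#' @return The baseline object with its original class.
#' @export
read_baseline_json <- function(path) {
  if (!file.exists(path)) stop("baseline file not found: ", path, call. = FALSE)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cls <- obj$baseline_class
  obj$baseline_class <- NULL
  if (!is.null(obj$window)) {
    obj$window <- structure(obj$window, class = "window_spec")
    obj$window$size <- as.integer(obj$window$size)
    obj$window$stride <- as.integer(obj$window$stride)
  }
  # JSON has no -Inf/Inf; they round-trip as strings
  for (f in c("lower", "upper")) {
    if (!is.null(obj[[f]]) && is.character(obj[[f]])) {
      obj[[f]] <- as.numeric(obj[[f]])
    }
  }
  structure(obj, class = cls)
}
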