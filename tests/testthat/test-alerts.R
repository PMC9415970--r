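test_that("huge alpha silences all alerts; held-out Gaussian tail matches 1 - Phi(1.5)", {
  set.seed(100)
  train <- fs(rnorm(10000))
  test <- fs(rnorm(10000))
  silent <- detect_alerts(test, fit_gaussian_baseline(train, alpha = 1e6),
                          "two_sided")
  expect_identical(silent$n_alerts, 0L)
  expect_equal(alert_fraction(silent), 0)

  b <- fit_gaussian_baseline(train, alpha = 1.5)
  al <- detect_alerts(test, b, "upper_only")
  p <- 1 - pnorm(1.5)
  se <- sqrt(p * (1 - p) / 10000)
  expect_lt(abs(alert_fraction(al) - p), 3 * se)
  expect_true(all(al$sides[al$flags] == "above"))
})

test_that("side rules mirror the deep/shallow breathing formulas", {
  b <- fit_gaussian_baseline(fs(rnorm(1000, 10, 1), kind = "moving_max"), 1.5)
  deep <- detect_alerts(fs(c(b$upper + 1, b$upper - 0.01, b$mu),
                           kind = "moving_max"), b, "upper_only")
  expect_identical(deep$flags, c(TRUE, FALSE, FALSE))
  expect_identical(deep$sides, c("above", "none", "none"))

  bm <- fit_gaussian_baseline(fs(rnorm(1000, 10, 1), kind = "moving_min"), 1.5)
  shallow <- detect_alerts(fs(c(bm$lower - 1, bm$lower + 0.01, bm$upper + 1),
                              kind = "moving_min"), bm, "lower_only")
  expect_identical(shallow$flags, c(TRUE, FALSE, FALSE))
  expect_identical(shallow$sides, c("below", "none", "none"))

  # strict inequalities: a value exactly at a threshold does not alert
  at <- detect_alerts(fs(c(b$upper, b$lower), kind = "moving_max"), b,
                      "two_sided")
  expect_identical(at$n_alerts, 0L)

  expect_error(detect_alerts(fs(1:10, kind = "amplitude"), b), "contract")
})

test_that("alert fraction is monotone in alpha and two-sided is the disjoint union", {
  set.seed(55)
  train <- fs(rnorm(2000))
  test <- fs(rnorm(2000, 0.5))
  prev <- 1
  for (alpha in c(0.5, 1, 1.5, 2, 3)) {
    b <- fit_gaussian_baseline(train, alpha)
    frac <- alert_fraction(detect_alerts(test, b, "two_sided"))
    expect_lte(frac, prev)
    prev <- frac
  }
  b <- fit_gaussian_baseline(train, 1)
  up <- detect_alerts(test, b, "upper_only")$flags
  lo <- detect_alerts(test, b, "lower_only")$flags
  two <- detect_alerts(test, b, "two_sided")$flags
  expect_identical(two, up | lo)
  expect_false(any(up & lo))
})

test_that("quantile thresholds applied to their own training data reproduce the fraction", {
  set.seed(12)
  x <- rnorm(3000)
  f <- fs(x)
  q <- fit_quantile_thresholds(f, 0.05, "two_sided")
  al <- detect_alerts(f, q, "two_sided")
  expect_lt(abs(alert_fraction(al) - 0.05), 1 / 3000 + 1e-12)
})

test_that("alert fractions count directly", {
  flags <- c(rep(TRUE, 3), rep(FALSE, 9))
  al <- detect_alerts(fs(ifelse(flags, 10, 0)),
                      structure(list(mu = 0, sigma = 1, alpha = 1, lower = -5,
                                     upper = 5, feature_kind = "amplitude",
                                     subject_id = "s"),
                                class = "gaussian_baseline"),
                      "upper_only")
  expect_equal(alert_fraction(al), 0.25)
  all_al <- detect_alerts(fs(rep(10, 4)),
                          structure(list(mu = 0, sigma = 1, alpha = 1,
                                         lower = -5, upper = 5,
                                         feature_kind = "amplitude",
                                         subject_id = "s"),
                                    class = "gaussian_baseline"),
                          "upper_only")
  expect_equal(alert_fraction(all_al), 1)
})

test_that("RA/LA counts split alerts around the training mean", {
  set.seed(200)
  train <- fs(rnorm(1000))
  b <- fit_gaussian_baseline(train, 1.5)

  none <- fs(rep(b$mu, 10))
  al0 <- detect_alerts(none, b, "two_sided")
  c0 <- ra_la_counts(none, al0, b)
  expect_identical(c0$ra, 0L)
  expect_identical(c0$la, 0L)

  shifted <- fs(rnorm(1000, mean = 3 * b$sigma))
  al <- detect_alerts(shifted, b, "two_sided")
  cc <- ra_la_counts(shifted, al, b)
  expect_gt(cc$ra, cc$la)
  expect_lte(cc$ra + cc$la, al$n_alerts)

  # values exactly at mu never count, even under a degenerate baseline
  bd <- fit_gaussian_baseline(fs(rep(1, 50)), 1.5)
  at_mu <- fs(rep(1, 5))
  ald <- detect_alerts(at_mu, bd, "two_sided")
  cd <- ra_la_counts(at_mu, ald, bd)
  expect_identical(cd$ra + cd$la, 0L)

  expect_error(ra_la_counts(fs(1:5), al, b), "alignment")
})

test_that("cohort summary groups by variant and feature with two-pass sd", {
  mk <- function(fraction, id, variant = "combined") {
    n <- 10L
    k <- as.integer(round(fraction * n))
    structure(list(values = rep(0, n),
                   flags = c(rep(TRUE, k), rep(FALSE, n - k)),
                   sides = rep("none", n), feature_kind = "amplitude",
                   subject_id = id, variant = variant, n_windows = n,
                   n_alerts = k, fraction = k / n),
              class = "alert_series")
  }
  single <- cohort_summary(list(mk(0.3, "a")))
  expect_equal(single$mean_fraction, 0.3)
  expect_equal(single$sd_fraction, 0)

  two <- cohort_summary(list(mk(0.2, "a"), mk(0.4, "b")))
  expect_equal(two$mean_fraction, 0.3)
  ora <- two_pass_mean_sd(c(0.2, 0.4), ddof = 1L)
  expect_equal(two$sd_fraction, ora$sd)

  mixed <- cohort_summary(list(mk(0.2, "a", "talking"), mk(0.4, "a")))
  expect_identical(nrow(mixed), 2L)
  expect_error(cohort_summary(list(mk(0.2, "a"), mk(0.4, "a"))), "duplicate")
  expect_error(cohort_summary(list()), "empty")
})

test_that("bivariate alerts flag points outside the frame exactly once", {
  set.seed(60)
  n <- 2000
  x <- fs(rnorm(n), kind = "dominant_frequency")
  y <- fs(rnorm(n), kind = "dominant_frequency")
  fr <- fit_bivariate_frame(x, y, 0.05, jitter_seed = 3,
                            jitter_halfwidth = 0)
  centroid <- fit_bivariate_frame(x, y, 0.05, jitter_seed = 3,
                                  jitter_halfwidth = 0)
  mid <- fs(rep(mean(x$values), 50), kind = "dominant_frequency")
  midy <- fs(rep(mean(y$values), 50), kind = "dominant_frequency")
  expect_identical(detect_bivariate_alerts(mid, midy, centroid)$n_alerts, 0L)

  # held-out draws from the same distribution land outside at about the
  # training rate
  xt <- fs(rnorm(n), kind = "dominant_frequency")
  yt <- fs(rnorm(n), kind = "dominant_frequency")
  al <- detect_bivariate_alerts(xt, yt, fr)
  se <- sqrt(0.05 * 0.95 / n)
  expect_lt(abs(alert_fraction(al) - 0.05), 4 * se)

  # a point outside on both axes is a single alert
  far <- fs(c(fr$x_upper + 10), kind = "dominant_frequency")
  fary <- fs(c(fr$y_upper + 10), kind = "dominant_frequency")
  both <- detect_bivariate_alerts(far, fary, fr)
  expect_identical(both$n_alerts, 1L)
  expect_error(detect_bivariate_alerts(x, fs(1:3, kind = "dominant_frequency"),
                                       fr), "alignment")
})
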