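test_that("Gaussian baseline matches a two-pass mean/sd computation", {
  f <- fs(1:100)
  b <- fit_gaussian_baseline(f, alpha = 1.5)
  want <- two_pass_mean_sd(1:100)
  expect_equal(b$mu, 50.5)
  expect_equal(b$mu, want$mean)
  expect_equal(b$sigma, want$sd)
  expect_equal(b$lower, want$mean - 1.5 * want$sd)
  expect_equal(b$upper, want$mean + 1.5 * want$sd)

  b1 <- fit_gaussian_baseline(f, alpha = 1.5, ddof = 1L)
  expect_equal(b1$sigma, stats::sd(1:100))
})

test_that("a constant series gives a degenerate but legal baseline", {
  b <- fit_gaussian_baseline(fs(rep(4.2, 50)), alpha = 2)
  expect_equal(b$mu, 4.2)
  expect_identical(b$sigma, 0)
  expect_equal(b$lower, 4.2)
  expect_equal(b$upper, 4.2)
  # any deviation from mu then alerts
  al <- detect_alerts(fs(c(4.2, 4.3, 4.1)), b, "two_sided")
  expect_identical(al$flags, c(FALSE, TRUE, TRUE))
})

test_that("Gaussian thresholds are symmetric about mu and linear in alpha", {
  set.seed(14)
  x <- rnorm(500, 3, 2)
  for (alpha in c(0.5, 1, 1.5, 3)) {
    b <- fit_gaussian_baseline(fs(x), alpha)
    expect_equal(b$upper - b$mu, b$mu - b$lower)
    expect_equal(b$upper - b$mu, alpha * b$sigma)
  }
  expect_error(fit_gaussian_baseline(fs(numeric(0))), "empty")
  expect_error(fit_gaussian_baseline(fs(x), alpha = 0), "positive")
})

test_that("two-sided quantile thresholds leave the stated fraction outside", {
  set.seed(4032)
  x <- rnorm(4032)
  q <- fit_quantile_thresholds(fs(x), 0.05, "two_sided")
  outside <- mean(x < q$lower | x > q$upper)
  expect_lt(abs(outside - 0.05), 1 / 4032 + 1e-12)
  # large-sample normal: thresholds near +/- 1.96
  expect_lt(abs(q$lower + 1.96), 0.15)
  expect_lt(abs(q$upper - 1.96), 0.15)

  up <- fit_quantile_thresholds(fs(x), 0.05, "upper_only")
  expect_identical(up$lower, -Inf)
  expect_lt(abs(mean(x > up$upper) - 0.05), 1 / 4032 + 1e-12)
})

test_that("quantile thresholds ignore the order of the values", {
  set.seed(8)
  x <- rgamma(300, 2)
  a <- fit_quantile_thresholds(fs(x), 0.1)
  b <- fit_quantile_thresholds(fs(sample(x)), 0.1)
  expect_identical(c(a$lower, a$upper), c(b$lower, b$upper))
})

test_that("a vanishing outlier fraction spans the whole data range", {
  set.seed(2)
  x <- rnorm(200)
  q <- fit_quantile_thresholds(fs(x), 1e-300, "two_sided")
  expect_equal(q$lower, min(x))
  expect_equal(q$upper, max(x))
  expect_identical(sum(x < q$lower | x > q$upper), 0L)
  expect_error(fit_quantile_thresholds(fs(x), 0), "0, 1")
  expect_error(fit_quantile_thresholds(fs(x), 1), "0, 1")
})

test_that("jitter makes tied integer features thresholdable", {
  # half the mass on one bin: raw quantiles would degenerate
  x <- c(rep(3, 500), sample(1:6, 500, replace = TRUE))
  f <- fs(x, kind = "dominant_frequency")
  q <- fit_quantile_thresholds(f, 0.05, "two_sided", jitter_seed = 99)
  expect_gt(q$upper - q$lower, 0)
  set.seed(99)
  xj <- x + runif(length(x), -0.5, 0.5)
  outside <- mean(xj < q$lower | xj > q$upper)
  expect_lt(abs(outside - 0.05), 1 / length(x) + 1e-12)
})

test_that("bivariate frame calibration hits the target training fraction", {
  set.seed(77)
  x <- fs(rnorm(4032), kind = "dominant_frequency")
  y <- fs(rnorm(4032), kind = "dominant_frequency")
  fr <- fit_bivariate_frame(x, y, 0.05, jitter_seed = 5)
  expect_lt(abs(fr$training_outside_fraction - 0.05), 1 / 4032 + 1e-12)

  # across sizes and seeds
  for (n in c(100, 500, 2000)) {
    for (seed in c(1, 2)) {
      set.seed(seed + n)
      a <- fs(rnorm(n), kind = "dominant_frequency")
      b <- fs(rnorm(n), kind = "dominant_frequency")
      fr <- fit_bivariate_frame(a, b, 0.05, jitter_seed = seed)
      expect_lt(abs(fr$training_outside_fraction - 0.05), 1 / n + 1e-12)
    }
  }
})

test_that("frame calibration agrees with a grid search over tail levels", {
  set.seed(31)
  n <- 4032
  xv <- rnorm(n)
  yv <- rnorm(n)
  fr <- fit_bivariate_frame(fs(xv, kind = "dominant_frequency"),
                            fs(yv, kind = "dominant_frequency"),
                            0.05, jitter_seed = 13)
  # reconstruct the jittered training points with the same seeded stream
  set.seed(13)
  xj <- xv + runif(n, -0.5, 0.5)
  yj <- yv + runif(n, -0.5, 0.5)
  grid <- seq(0.001, 0.05, by = 0.0005)
  best <- Inf
  for (t in grid) {
    xl <- unname(quantile(xj, c(t / 2, 1 - t / 2), type = 7))
    yl <- unname(quantile(yj, c(t / 2, 1 - t / 2), type = 7))
    frac <- brute_outside_fraction(xj, yj, xl, yl)
    best <- min(best, abs(frac - 0.05))
  }
  expect_lte(abs(fr$training_outside_fraction - 0.05), best + 1 / n + 1e-12)
  # and the fitted limits reproduce the reported fraction on the jittered data
  got <- brute_outside_fraction(xj, yj, c(fr$x_lower, fr$x_upper),
                                c(fr$y_lower, fr$y_upper))
  expect_equal(got, fr$training_outside_fraction)
})

test_that("frame jitter is reproducible and degenerate axes calibrate", {
  set.seed(6)
  a <- fs(rnorm(800), kind = "dominant_frequency")
  b <- fs(rnorm(800), kind = "dominant_frequency")
  f1 <- fit_bivariate_frame(a, b, 0.05, jitter_seed = 42)
  f2 <- fit_bivariate_frame(a, b, 0.05, jitter_seed = 42)
  expect_identical(unclass(f1), unclass(f2))
  f3 <- fit_bivariate_frame(a, b, 0.05, jitter_seed = 43)
  expect_false(identical(c(f1$x_lower, f1$x_upper), c(f3$x_lower, f3$x_upper)))

  # constant y axis with no jitter: all outliers come from x
  const <- fs(rep(2, 800), kind = "dominant_frequency")
  fd <- fit_bivariate_frame(a, const, 0.05, jitter_seed = 1,
                            jitter_halfwidth = 0)
  expect_lt(abs(fd$training_outside_fraction - 0.05), 1 / 800 + 1e-12)
  expect_identical(fd$y_lower, 2)
  expect_identical(fd$y_upper, 2)
  expect_error(fit_bivariate_frame(a, fs(rnorm(10)), 0.05), "alignment")
})

test_that("baselines survive a JSON round-trip, including infinite bounds", {
  dir <- withr::local_tempdir()
  g <- fit_gaussian_baseline(fs(rnorm(100)), 1.5)
  p <- file.path(dir, "g.json")
  write_baseline_json(g, p)
  g2 <- read_baseline_json(p)
  expect_s3_class(g2, "gaussian_baseline")
  expect_equal(g2$mu, g$mu)
  expect_equal(g2$sigma, g$sigma)
  expect_equal(g2$upper, g$upper)
  expect_equal(g2$window$size, g$window$size)

  q <- fit_quantile_thresholds(fs(rnorm(100)), 0.05, "upper_only")
  p <- file.path(dir, "q.json")
  write_baseline_json(q, p)
  q2 <- read_baseline_json(p)
  expect_identical(q2$lower, -Inf)
  expect_equal(q2$upper, q$upper)

  fr <- fit_bivariate_frame(fs(rnorm(100), kind = "dominant_frequency"),
                            fs(rnorm(100), kind = "dominant_frequency"), 0.05)
  p <- file.path(dir, "f.json")
  write_baseline_json(fr, p)
  fr2 <- read_baseline_json(p)
  expect_s3_class(fr2, "bivariate_frame")
  expect_equal(fr2$x_upper, fr$x_upper)
  expect_equal(fr2$training_outside_fraction, fr$training_outside_fraction)
})
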