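# Independent brute-force oracles and small constructors used across tests.

# Feature series built directly from values, for baseline/alert tests that
# do not need a trace.
fs <- function(values, kind = "amplitude", size = 12L, stride = 1L,
               enumeration = "all_full_windows", subject = "oracle",
               rate = 12) {
  structure(list(kind = kind, values = as.numeric(values),
                 window = window_spec(size, stride, enumeration),
                 subject_id = subject, sampling_rate = rate),
            class = "feature_series")
}

# O(N*W) per-window extremum scan, no shared code with the implementation.
brute_extremum <- function(x, W, stride = 1L, enumeration = "all_full_windows",
                           which = "max") {
  n <- length(x)
  full <- (n - W) %/% stride + 1L
  k <- if (enumeration == "drop_last") full - 1L else full
  f <- if (which == "max") max else min
  vapply(seq_len(k), function(j) {
    s <- (j - 1L) * stride + 1L
    v <- x[s]
    if (W > 1L) for (t in (s + 1L):(s + W - 1L)) v <- f(v, x[t])
    v
  }, numeric(1))
}

# O(W^2) direct DFT magnitude, summed term by term.
brute_dft_mag <- function(w) {
  W <- length(w)
  vapply(0:(W - 1L), function(j) {
    re <- 0; im <- 0
    for (t in 0:(W - 1L)) {
      ang <- -2 * pi * j * t / W
      re <- re + w[t + 1L] * cos(ang)
      im <- im + w[t + 1L] * sin(ang)
    }
    sqrt(re^2 + im^2)
  }, numeric(1))
}

brute_dft_argmax <- function(w, demean = TRUE, bin_range = "positive_bins") {
  if (demean) w <- w - sum(w) / length(w)
  mag <- brute_dft_mag(w)
  W <- length(w)
  if (bin_range == "positive_bins") {
    bins <- 1:(W %/% 2)
    bins[which.max(mag[bins + 1L])]
  } else {
    which.max(mag) - 1L
  }
}

# Two-pass mean / sd, population convention.
two_pass_mean_sd <- function(x, ddof = 0L) {
  n <- length(x)
  m <- sum(x) / n
  ss <- 0
  for (v in x) ss <- ss + (v - m)^2
  list(mean = m, sd = sqrt(ss / (n - ddof)))
}

# Fraction of (x, y) points outside a rectangle, written independently.
brute_outside_fraction <- function(x, y, xlim, ylim) {
  cnt <- 0L
  for (i in seq_along(x)) {
    if (x[i] < xlim[1] || x[i] > xlim[2] || y[i] < ylim[1] || y[i] > ylim[2]) {
      cnt <- cnt + 1L
    }
  }
  cnt / length(x)
}
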