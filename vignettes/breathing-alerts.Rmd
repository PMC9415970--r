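---
title: "Personal breathing-pattern baselines and alert generation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Personal breathing-pattern baselines and alert generation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(breathalert)
```

## The model

A respiration belt produces a one-dimensional extension signal `s(i)` whose
oscillation tracks the wearer's breathing. `breathalert` treats alerting as
a per-person outlier-detection problem: learn the empirical distribution of
a windowed feature on a resting segment of *that wearer's own* signal, and
flag test windows whose feature value falls outside thresholds derived from
that distribution. Nothing is pooled across people — resting breathing
differs enough between individuals that a population threshold would be
meaningless, and this is the package's central assumption.

Four features are computed on sliding windows (stride 1 by default):
moving maximum `M(i)`, moving minimum `m(i)`, amplitude
`A(i) = M(i) − m(i)`, and the dominant DFT bin
`f(i) = argmax_j |FFT(w_i)_j|`. The first three live in belt units and
proxy breath depth; the last is a unitless bin index proxying breathing
rate (bin `j` ≙ `j · rate / W` Hz).

Three baseline families convert a training feature series into thresholds:

* **Gaussian** (`fit_gaussian_baseline`): `μ ± α·σ`. The default
  `α = 1.5` standard deviations is the operating point all the field
  results are reported at; α trades sensitivity against specificity and is
  exposed everywhere.
* **Quantile** (`fit_quantile_thresholds`): thresholds at empirical
  quantiles so that a stated fraction (default 5%) of training values lie
  outside. This is the default rule for the dominant-frequency feature,
  whose integer values make the Gaussian summary coarse.
* **Bivariate frame** (`fit_bivariate_frame`): for two synchronous
  channels, an axis-aligned rectangle calibrated so a stated fraction of
  jittered training points fall outside.

Detection (`detect_alerts`) uses strict inequalities — a value exactly at a
threshold does not alert — and each feature has a canonical side:
upper-only for `M`, `A` and `f` (too deep / too fast), lower-only for `m`
(too shallow). Two-sided detection is used for the RA/LA window-size
sensitivity analysis, where alerts are split by whether their value sits
right or left of the training mean.

## Train/test conventions

Field mode trains on the resting activities preceding the run (the initial
sitting and walking phases, ~2880 samples at 12 Hz) and tests on the
running phase (~1440 samples). Literature mode trains on the first half of
a recording and tests on the second. The three talking variants
(`combined`, `talking`, `not_talking`) filter the raw samples by the
talking flag *before* feature extraction, so each variant owns its feature
series and baseline; filtering afterwards would let windows straddle the
removed segments.

## Window bookkeeping

Two window-enumeration conventions coexist deliberately. For a trace of
length `N`, stride 1:

* extrema and amplitude enumerate **all full windows** — `N − W + 1`
  values (start indices `0 … N−W`; 2869 values for `N = 2880`, `W = 12`);
* dominant frequency **drops the last window** — `N − W` values (start
  indices `0 … N−W−1`; 2832 values for `N = 2880`, `W = 48`).

The two index ranges are inconsistent with each other by one window; both
are kept, each as the default for its feature family, and both are
selectable via `window_spec(enumeration =)`. Nothing downstream depends on
the extra window beyond the bookkeeping itself.

Default window sizes: 12 samples (1 s at 12 Hz) for extrema/amplitude and
48 samples (4 s) for the FFT in field mode; 128 samples for both in
literature mode (1 s at 128 Hz). The RA/LA sweep (`ra_la_sweep`) exists
precisely because the extremum window size is a free choice; mid-range
sizes (roughly 4–19 samples) give the most consistent RA > LA signature,
and 12 sits in the middle of that band while also being a round second.

## Numerical choices

* **FFT mode.** The argmax-of-`|FFT|` definition taken literally includes
  bin 0 (the window mean) and the mirrored upper half of the spectrum. A
  belt signal has a large positive mean, which would make bin 0 dominant
  in every window. The default therefore demeans each window and restricts
  the argmax to bins `1 … ⌊W/2⌋`; `fft_mode = "paper_literal"` keeps the
  raw definition (no demeaning, all `W` bins) for strict replication. Ties
  break to the smallest bin, giving a deterministic result; for a real
  signal the upper-half bins are exact mirror ties, which is the other
  reason the positive-bin default exists. No tapering or zero-padding is
  applied.
* **Standard deviation** uses the population convention (divide by `n`),
  switchable to `n−1` via `ddof`; at `n ≈ 2869` the difference is in the
  fourth decimal, but determinism requires picking one.
* **Quantiles** are `stats::quantile` type 7 (linear interpolation between
  order statistics) — again a fixed convention so results are
  bit-reproducible.
* **Jitter** for integer-valued features is uniform on `± 0.5`, half the
  spacing of the frequency-bin grid, drawn from a seeded local RNG stream
  that does not disturb the caller's RNG state. The same seed always
  yields bit-identical thresholds.
* **Frame calibration.** "5% of training points outside a rectangle"
  under-determines the per-axis thresholds: symmetric per-axis tails of
  2.5% each would overshoot (the marginal tails union to more than 5%
  whenever the axes' outliers don't coincide). The per-axis tail level is
  therefore found by bisection (60 iterations on `(0, p]`, widening the
  bracket if needed) until the jittered training outside-fraction matches
  the joint target; with `n` training points the achievable fractions are
  multiples of `1/n`, so agreement is to within `1/n` and the calibrated
  count is typically the integer nearest `p·n` regardless of seed.
* **Degenerate inputs.** A constant training series is legal: `σ = 0`
  collapses the Gaussian thresholds onto the mean, so any deviation
  alerts (the CLI logs a warning at train time). A constant axis in the
  frame contributes no outliers and calibration proceeds on the other
  axis. Values exactly equal to the mean count toward neither RA nor LA.

## The simulator

`simulate_trace` generates
`s(i) = baseline + drift(i) + a(i)·sin(φ(i)) + ε(i)` where the sinusoid
rate and base amplitude switch with the protocol's activity phases, the
phase `φ` accumulates continuously across phase boundaries (no spectral
splatter at transitions), each breath cycle draws an amplitude multiplier
with the activity's coefficient of variation (doubled while talking),
talking additionally scales the amplitude by a factor, `drift` is a random
walk (belt units per √s, emulating slow belt-position creep), and `ε` is
white noise. All randomness flows from one seed through independent
substreams (initial phase, breath jitter, drift, noise), so any component
can be zeroed without changing the others' realizations.

Defaults: sitting 0.25 Hz at amplitude 1.0, walking 0.30 Hz at 1.2,
running 0.60 Hz at 2.0 (belt units); talking factor 0.8 with doubled
amplitude CV; noise SD 0.1, drift SD 0.05, baseline level 10. These are
fixture values chosen once so that resting and running feature
distributions overlap partially rather than separating trivially — they
are not physiological claims, and they cannot be validated against the
field recordings, which are not public. What the simulator does *not*
emulate: motion artefacts, sensor saturation, irregular breath-to-breath
timing, posture changes within a phase, or any coupling between the two
channels of the bivariate setting. Passing tests therefore demonstrate
that the pipeline's bookkeeping, calibration and detection behave as
specified on signals with known structure — not that the alert fractions
reported on real field data would be reproduced.

## What the tests check, and at what sizes

The suite verifies every feature against independent brute-force oracles
(per-window scans for the extrema on 1000 random instances; an `O(W²)`
direct DFT on 200 random windows up to `W = 64`), the Gaussian tail rate
at `α = 1.5` on 10,000 held-out draws (expected `1 − Φ(1.5) ≈ 0.0668`),
frame calibration at `n = 4032` against a grid search over tail levels,
and the protocol arithmetic (5760/2880/1440 and 8064/4032 samples; 2869
and 2832 windows). The end-to-end qualitative check runs 10 simulated
subjects with elevated running amplitude and rate and asserts that
amplitude- and frequency-alert fractions on the running phase exceed those
on the post-run sitting phase, and that RA > LA holds for at least 9 of 10
subjects across extremum window sizes 4–19. Ten subjects at 5760 samples
keeps the full suite under a minute on one core while leaving the
binomial margins of the stochastic assertions comfortable.

## Limitations

Alert fractions count windows, and overlapping windows are heavily
correlated — a single deep breath alerts many consecutive windows, so a
fraction is not a probability of an anomalous *breath*. The Gaussian
baseline assumes the feature distribution is summarised adequately by its
first two moments; resting amplitude distributions are typically
right-skewed, making upper thresholds conservative. The frame is
axis-aligned and cannot represent correlated two-channel outliers. None
of the thresholds adapt over time; a baseline trained once is applied
unchanged, which matches the train-then-monitor deployment model but
ignores drift beyond what the training segment contained.
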