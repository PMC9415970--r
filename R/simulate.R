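#' Per-activity generator parameters
#'
#' Parameters of the synthetic breathing signal during one activity.
#' The signal model is a sinusoid (rate, amplitude) with per-breath
#' amplitude jitter plus white noise; talking damps the amplitude and
#' doubles the per-breath jitter, emulating the irregular, shallower
#' breathing of speech.
#'
#' @param breathing_rate Breathing frequency in Hz; must resolve at the
#'   protocol's sampling rate (rate < rate/2).
#' @param breathing_amplitude Peak sinusoid amplitude in belt units.
#' @param amplitude_cv Coefficient of variation of the per-breath
#'   amplitude multiplier, >= 0.
#' @param talking_amplitude_factor Multiplier applied to the amplitude
#'   while the talking flag is set, > 0.
#' @param noise_sd White-noise standard deviation in belt units.
#' @return An object of class `activity_params`.
#' @export
activity_params <- function(breathing_rate, breathing_amplitude,
                            amplitude_cv = 0.1,
                            talking_amplitude_factor = 0.8,
                            noise_sd = 0.1) {
  stopifnot(breathing_rate > 0, breathing_amplitude >= 0, amplitude_cv >= 0,
            talking_amplitude_factor > 0, noise_sd >= 0)
  structure(list(breathing_rate = breathing_rate,
                 breathing_amplitude = breathing_amplitude,
                 amplitude_cv = amplitude_cv,
                 talking_amplitude_factor = talking_amplitude_factor,
                 noise_sd = noise_sd),
            class = "activity_params")
}

#' Default per-activity parameter set
#'
#' Fixture values, not physiological claims: sitting 0.25 Hz at unit
#' amplitude, walking slightly faster and larger, running markedly faster
#' and deeper, so rest and run feature distributions overlap partially
#' rather than separating trivially.
#'
#' @return Named list of [activity_params()] keyed by activity label.
#' @export
default_activity_params <- function() {
  list(
    sitting = activity_params(0.25, 1.0),
    walking = activity_params(0.30, 1.2),
    running = activity_params(0.60, 2.0),
    other   = activity_params(0.25, 1.0)
  )
}

#' Protocol specification
#'
#' An ordered list of activity phases with durations and an optional
#' within-phase talking window, plus global signal parameters.
#'
#' @param phases List of phases; each a list with `activity` (label),
#'   `duration_s` (seconds) and optional `talk_window_s`
#'   (`c(start, end)` seconds within the phase, half-open).
#' @param sampling_rate Hz.
#' @param baseline_level Mean belt extension in belt units.
#' @param drift_sd Random-walk drift scale, belt units per sqrt(second).
#' @return An object of class `protocol_spec`.
#' @export
protocol_spec <- function(phases, sampling_rate, baseline_level = 10,
                          drift_sd = 0.05) {
  stopifnot(length(phases) > 0, sampling_rate > 0)
  for (ph in phases) {
    stopifnot(is.character(ph$activity), ph$duration_s > 0)
    n <- ph$duration_s * sampling_rate
    if (abs(n - round(n)) > 1e-9) {
      stop("phase duration must yield an integer sample count", call. = FALSE)
    }
  }
  structure(list(phases = phases, sampling_rate = sampling_rate,
                 baseline_level = baseline_level, drift_sd = drift_sd),
            class = "protocol_spec")
}

#' The canonical field protocol
#'
#' Sit, walk, run, sit again — 2 min each at 12 Hz (5760 samples total),
#' with talking allowed only during the second minute of each phase.
#'
#' @return A [protocol_spec()].
#' @export
field_protocol <- function() {
  phase <- function(act) list(activity = act, duration_s = 120,
                              talk_window_s = c(60, 120))
  protocol_spec(
    phases = list(phase("sitting"), phase("walking"),
                  phase("running"), phase("sitting")),
    sampling_rate = 12
  )
}

#' The literature-data protocol shape
#'
#' A single 63-s resting phase at 128 Hz (8064 samples), two channels,
#' no activity change and no talking — the shape of a public
#' multi-channel physiological dataset's trials.
#'
#' @return A [protocol_spec()].
#' @export
deap_protocol <- function() {
  protocol_spec(
    phases = list(list(activity = "sitting", duration_s = 63,
                       talk_window_s = NULL)),
    sampling_rate = 128
  )
}

protocol_labels <- function(protocol) {
  fs <- protocol$sampling_rate
  activity <- character(0)
  talking <- logical(0)
  for (ph in protocol$phases) {
    n <- round(ph$duration_s * fs)
    t_within <- (seq_len(n) - 1L) / fs
    talk <- if (is.null(ph$talk_window_s)) rep(FALSE, n) else {
      t_within >= ph$talk_window_s[1L] & t_within < ph$talk_window_s[2L]
    }
    activity <- c(activity, rep(ph$activity, n))
    talking <- c(talking, talk)
  }
  list(activity = activity, talking = talking)
}

#' Simulate a respiration-belt trace under a protocol
#'
#' Generates s(i) = baseline + random-walk drift + a(i) sin(phi(i)) +
#' noise, where the sinusoid rate and base amplitude switch with the
#' protocol's activity phases, the instantaneous phase phi accumulates
#' continuously across phase boundaries, each breath cycle draws an
#' amplitude multiplier with the activity's coefficient of variation
#' (doubled while talking), and talking also scales the amplitude by the
#' activity's talking factor. All randomness flows from `seed` through
#' independent substreams (initial phase, drift, breath jitter, noise),
#' so any component can be switched off without perturbing the others.
#'
#' @param protocol A [protocol_spec()].
#' @param params_by_activity Named list of [activity_params()] covering
#'   every activity in the protocol.
#' @param seed Integer seed; identical seeds give identical traces.
#' @param subject_id Subject identifier to attach.
#' @return A [respiration_trace()] with activity and talking labels.
#' @export
simulate_trace <- function(protocol, params_by_activity = default_activity_params(),
                           seed = 1L, subject_id = "sim") {
  stopifnot(inherits(protocol, "protocol_spec"))
  labs <- protocol_labels(protocol)
  acts <- unique(labs$activity)
  missing <- setdiff(acts, names(params_by_activity))
  if (length(missing) > 0L) {
    stop("parameter error: no activity_params for: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  fs <- protocol$sampling_rate
  for (a in acts) {
    if (params_by_activity[[a]]$breathing_rate >= fs / 2) {
      stop("parameter error: breathing_rate must be below the Nyquist rate",
           call. = FALSE)
    }
  }
  n <- length(labs$activity)
  sub <- with_local_seed(seed, sample.int(.Machine$integer.max, 4L))

  pick <- function(field) {
    vapply(labs$activity, function(a) params_by_activity[[a]][[field]],
           numeric(1), USE.NAMES = FALSE)
  }
  rate <- pick("breathing_rate")
  base_amp <- pick("breathing_amplitude")
  cv <- pick("amplitude_cv")
  talk_factor <- pick("talking_amplitude_factor")
  noise_sd <- pick("noise_sd")

  phi0 <- with_local_seed(sub[1L], stats::runif(1, 0, 2 * pi))
  phi <- phi0 + cumsum(2 * pi * rate / fs)

  # one amplitude multiplier per breath cycle, cv taken at the breath's
  # first sample (doubled while talking)
  breath <- floor(phi / (2 * pi))
  breath_id <- match(breath, unique(breath))
  first_idx <- which(!duplicated(breath_id))
  cv_at_start <- cv[first_idx] * ifelse(labs$talking[first_idx], 2, 1)
  z <- with_local_seed(sub[2L], stats::rnorm(length(first_idx)))
  mult <- pmax(1 + cv_at_start * z, 0)
  amp <- base_amp * ifelse(labs$talking, talk_factor, 1) * mult[breath_id]

  drift <- with_local_seed(sub[3L], cumsum(
    stats::rnorm(n, 0, protocol$drift_sd / sqrt(fs))))
  noise <- with_local_seed(sub[4L], stats::rnorm(n, 0, 1)) * noise_sd

  s <- protocol$baseline_level + drift + amp * sin(phi) + noise
  respiration_trace(s, fs, activity = labs$activity, talking = labs$talking,
                    subject_id = subject_id)
}

#' Simulate a two-channel trace
#'
#' Respiration channel as [simulate_trace()]; the second channel (ocular
#' movement) is an independent oscillation-plus-noise process of the same
#' length and rate with its own parameters and substream.
#'
#' @param protocol A [protocol_spec()].
#' @param resp_params Named list of [activity_params()] for respiration.
#' @param ocular_params Named list of [activity_params()] for the second
#'   channel. Default: a faster (2 Hz), unit-amplitude oscillation.
#' @param seed Integer seed.
#' @param subject_id Subject identifier.
#' @return A [bivariate_trace()].
#' @export
simulate_bivariate <- function(protocol,
                               resp_params = default_activity_params(),
                               ocular_params = NULL,
                               seed = 1L, subject_id = "sim") {
  stopifnot(inherits(protocol, "protocol_spec"))
  if (is.null(ocular_params)) {
    acts <- unique(protocol_labels(protocol)$activity)
    ocular_params <- stats::setNames(
      rep(list(activity_params(2.0, 1.0, amplitude_cv = 0.2, noise_sd = 0.2)),
          length(acts)), acts)
  }
  sub <- with_local_seed(seed, sample.int(.Machine$integer.max, 2L))
  a <- simulate_trace(protocol, resp_params, seed = sub[1L],
                      subject_id = subject_id)
  b <- simulate_trace(protocol, ocular_params, seed = sub[2L],
                      subject_id = subject_id)
  bivariate_trace(a, b)
}

#' Split a trace into training and test segments
#'
#' Field mode trains on the resting activities preceding the run (the
#' initial sitting and walking phases) and tests on the running phase;
#' literature mode trains on the first half of the samples and tests on
#' the second half.
#'
#' @param trace A labelled [respiration_trace()].
#' @param mode `"field"` or `"literature"`.
#' @return List with elements `train` and `test` (traces). Field mode
#'   additionally returns `rest2`, the post-run sitting phase, usable as
#'   a same-condition control segment.
#' @export
training_split <- function(trace, mode = c("field", "literature")) {
  stopifnot(inherits(trace, "respiration_trace"))
  mode <- match.arg(mode)
  n <- length(trace$samples)
  if (mode == "literature") {
    half <- n %/% 2L
    return(list(train = trace_slice(trace, seq_len(half)),
                test = trace_slice(trace, (half + 1L):n)))
  }
  if (is.null(trace$activity)) {
    stop("field-mode split needs activity labels", call. = FALSE)
  }
  run_idx <- which(trace$activity == "running")
  if (length(run_idx) == 0L) {
    stop("field-mode split needs a running phase", call. = FALSE)
  }
  first_run <- run_idx[1L]
  train_idx <- which(trace$activity %in% c("sitting", "walking") &
                     seq_len(n) < first_run)
  after_run <- which(trace$activity != "running" & seq_len(n) > max(run_idx))
  out <- list(train = trace_slice(trace, train_idx),
              test = trace_slice(trace, run_idx))
  if (length(after_run) > 0L) out$rest2 <- trace_slice(trace, after_run)
  out
}

#' Filter a trace by talking variant
#'
#' The three train/test variants keep only talking samples, only
#' non-talking samples, or all samples. Filtering happens on the raw
#' trace, before feature extraction, so each variant has its own feature
#' series and baseline.
#'
#' @param trace A [respiration_trace()] with talking flags (not needed
#'   for `"combined"`).
#' @param variant `"combined"`, `"talking"` or `"not_talking"`.
#' @return A [respiration_trace()].
#' @export
variant_filter <- function(trace, variant = c("combined", "talking", "not_talking")) {
  stopifnot(inherits(trace, "respiration_trace"))
  variant <- match.arg(variant)
  if (variant == "combined") return(trace)
  if (is.null(trace$talking)) {
    stop("variant filtering needs talking flags", call. = FALSE)
  }
  keep <- if (variant == "talking") trace$talking else !trace$talking
  if (!any(keep)) stop("variant '", variant, "' leaves no samples", call. = FALSE)
  trace_slice(trace, keep)
}
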