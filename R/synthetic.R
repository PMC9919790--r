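#' Configuration for the synthetic circadian heart-rate generator
#'
#' The generator emulates the statistical structure that window-centred
#' binning exploits in real tracker data: strong cross-day similarity at the
#' same minute of day (daily routine), within-day nonstationarity (a low,
#' flat sleep period and an elevated, variable active period), day-level
#' random effects, and minute-level autocorrelated noise. Step counts are
#' exactly zero throughout the sleep window — the operational definition of
#' the "inactive" period.
#'
#' @param n_days number of days to generate.
#' @param baseline_bpm resting-level heart rate (beats/min).
#' @param circadian_amplitude amplitude of the smooth 24-h sinusoid
#'   (beats/min); its trough is centred in `sleep_window`.
#' @param sleep_window,active_window `[start, end)` minute-of-day windows
#'   (0-based, within 0–1439).
#' @param activity_boost_bpm extra heart rate during the (jittered) active
#'   window (beats/min).
#' @param routine_jitter_min each day's active window shifts by an integer
#'   uniform on `[-routine_jitter_min, routine_jitter_min]` minutes,
#'   emulating imperfect routine.
#' @param day_effect_sd standard deviation of the i.i.d. per-day level shift
#'   (beats/min).
#' @param ar1_rho lag-1 autocorrelation of the minute-level noise, in
#'   `[0, 1)`.
#' @param noise_sd marginal standard deviation of the minute-level AR(1)
#'   noise (beats/min); innovations are scaled by `sqrt(1 - ar1_rho^2)` so
#'   the marginal sd stays `noise_sd` for any `ar1_rho`.
#' @param seed integer seed; the same configuration always generates the
#'   same data.
#' @return a `synth_config` list.
#' @export
synth_config <- function(n_days = 30L,
                         baseline_bpm = 62,
                         circadian_amplitude = 10,
                         sleep_window = c(60L, 420L),
                         active_window = c(840L, 1080L),
                         activity_boost_bpm = 25,
                         routine_jitter_min = 10L,
                         day_effect_sd = 2,
                         ar1_rho = 0.7,
                         noise_sd = 3,
                         seed = 1L) {
  ok_window <- function(w) {
    length(w) == 2L && all(w == round(w)) && w[1] >= 0 && w[2] <= 1440 && w[1] < w[2]
  }
  if (!is_count(n_days)) stop_format("n_days must be a positive integer")
  if (!is_number(baseline_bpm, min = 1e-8)) stop_format("baseline_bpm must be > 0")
  if (!is_number(circadian_amplitude, min = 0)) stop_format("circadian_amplitude must be >= 0")
  if (!ok_window(sleep_window) || !ok_window(active_window)) {
    stop_format("windows must be [start, end) with 0 <= start < end <= 1440")
  }
  if (!is_number(activity_boost_bpm, min = 0)) stop_format("activity_boost_bpm must be >= 0")
  if (!is_count(routine_jitter_min, min = 0L)) stop_format("routine_jitter_min must be >= 0")
  if (!is_number(day_effect_sd, min = 0)) stop_format("day_effect_sd must be >= 0")
  if (!is_number(ar1_rho, min = 0) || ar1_rho >= 1) stop_format("ar1_rho must be in [0, 1)")
  if (!is_number(noise_sd, min = 0)) stop_format("noise_sd must be >= 0")
  if (!is_count(seed, min = -.Machine$integer.max)) stop_format("seed must be an integer")
  structure(list(n_days = as.integer(n_days),
                 baseline_bpm = baseline_bpm,
                 circadian_amplitude = circadian_amplitude,
                 sleep_window = as.integer(sleep_window),
                 active_window = as.integer(active_window),
                 activity_boost_bpm = activity_boost_bpm,
                 routine_jitter_min = as.integer(routine_jitter_min),
                 day_effect_sd = day_effect_sd,
                 ar1_rho = ar1_rho,
                 noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "synth_config")
}

# Deterministic part of the model shared by generate_days and
# generate_sample_stream: baseline + circadian sinusoid, trough centred in
# the sleep window.
synth_circadian <- function(config, minutes = 0:1439) {
  trough <- mean(config$sleep_window)
  config$baseline_bpm -
    config$circadian_amplitude * cos(2 * pi * (minutes - trough) / 1440)
}

# Per-day random components, in a fixed draw order so that streams and
# matrices generated from the same seed agree minute for minute.
synth_day_components <- function(config) {
  jitter <- if (config$routine_jitter_min > 0) {
    sample.int(2L * config$routine_jitter_min + 1L, 1L) - config$routine_jitter_min - 1L
  } else 0L
  delta <- rnorm(1L, 0, config$day_effect_sd)
  innov_sd <- config$noise_sd * sqrt(1 - config$ar1_rho^2)
  e0 <- rnorm(1L, 0, config$noise_sd)  # stationary start
  eps <- as.numeric(stats::filter(rnorm(1440L, 0, innov_sd),
                                  config$ar1_rho, method = "recursive",
                                  init = e0))
  list(jitter = jitter, delta = delta, eps = eps)
}

synth_day_hr <- function(config, circ, comp) {
  act <- numeric(1440L)
  a <- pmin(pmax(config$active_window + comp$jitter, 0L), 1440L)
  if (a[1] < a[2]) act[(a[1] + 1L):a[2]] <- config$activity_boost_bpm
  circ + act + comp$delta + comp$eps
}

#' Generate synthetic minute-level heart-rate and step-count days
#'
#' Heart rate for day `d`, minute `m` is
#' `baseline + circadian(m) + activity(d, m) + delta_d + eps(d, m)`, where
#' `circadian` is a 24-h sinusoid with trough centred in the sleep window,
#' `activity` adds `activity_boost_bpm` on the day's jittered active window,
#' `delta_d` is an i.i.d. normal day effect, and `eps` is a per-day AR(1)
#' noise process with marginal sd `noise_sd`. Step counts are 0 on every
#' sleep-window minute, Poisson(40) on the jittered active window, and
#' Poisson(2) elsewhere.
#'
#' @param config a [synth_config()].
#' @return list with `hr` and `steps`, both [day_matrix()] objects of
#'   dimension `n_days x 1440` with no missing cells; rows are labelled with
#'   synthetic consecutive dates.
#' @export
generate_days <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  circ <- synth_circadian(config)
  hr <- matrix(NA_real_, config$n_days, 1440L)
  steps <- matrix(NA_real_, config$n_days, 1440L)
  sleep_idx <- (config$sleep_window[1] + 1L):config$sleep_window[2]
  with_seed(config$seed, {
    for (d in seq_len(config$n_days)) {
      comp <- synth_day_components(config)
      hr[d, ] <- synth_day_hr(config, circ, comp)
      a <- pmin(pmax(config$active_window + comp$jitter, 0L), 1440L)
      s <- rpois(1440L, 2)
      if (a[1] < a[2]) s[(a[1] + 1L):a[2]] <- rpois(a[2] - a[1], 40)
      s[sleep_idx] <- 0L
      steps[d, ] <- s
    }
  })
  days <- format(seq(as.Date("2022-03-01"), by = 1, length.out = config$n_days))
  # steps legitimately contain zeros, so they bypass the heart-rate
  # positivity check of day_matrix()
  list(hr = day_matrix(hr, days = days),
       steps = structure(`dimnames<-`(steps, list(days, sprintf("m%04d", 0:1439))),
                         col_offset = 0L, class = "day_matrix"))
}

#' Emit a 5-second raw sample stream for one synthetic day
#'
#' Produces the device-cadence view of the same generative model: 12 samples
#' per minute whose values are the day's minute-level model value plus
#' independent within-minute jitter. Feeding the stream through
#' [to_minute_series()] recovers the minute value up to jitter averaging
#' (`jitter_sd / sqrt(12)`); with `jitter_sd = 0` the recovery is exact and
#' matches the corresponding [generate_days()] row for the same seed.
#'
#' @param config a [synth_config()].
#' @param day 1-based day index into the configuration's days.
#' @param jitter_sd within-minute sample jitter sd (beats/min), default 1.
#' @return a [raw_samples()] series of `1440 * 12` samples.
#' @export
generate_sample_stream <- function(config = synth_config(), day = 1L,
                                   jitter_sd = 1) {
  stopifnot(inherits(config, "synth_config"))
  if (!is_count(day) || day > config$n_days) {
    stop_format("`day` must be in 1..%d", config$n_days)
  }
  if (!is_number(jitter_sd, min = 0)) stop_format("jitter_sd must be >= 0")
  hr <- generate_days(config)$hr
  minute_vals <- dm_values(hr)[day, ]
  date <- as.Date(rownames(hr)[day])
  # 12 five-second samples per minute; jitter drawn from a stream-specific
  # seed so matrix and stream generation stay independently reproducible
  jit <- with_seed(config$seed + 7919L * as.integer(day),
                   rnorm(1440L * 12L, 0, jitter_sd))
  values <- rep(minute_vals, each = 12L) + jit
  values <- pmax(values, 1e-6)  # device values are positive by construction
  day_start <- as.POSIXct(paste(format(date), "00:00:00"), tz = "UTC")
  time <- day_start + seq(0L, by = 5L, length.out = 1440L * 12L)
  raw_samples(time, values, subject_id = "synthetic",
              nominal_interval_s = 5L)
}
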