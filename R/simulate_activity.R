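#' Closed-form injury factor of the activity generator
#'
#' Multiplicative suppression applied to the circadian template on and after
#' the surgery day: 1 before surgery, `1 - dip_depth` on day 0, then an
#' exponential relaxation toward `recovery_gain`.
#'
#' @param day integer-valued day index relative to surgery (day 0 = surgery).
#' @param preset an [activity_preset()].
#' @return numeric vector of multiplicative factors.
#' @export
#' @examples
#' p <- study_activity_presets()$bilateral_free
#' injury_factor(-2:5, p)
injury_factor <- function(day, preset) {
  stopifnot(inherits(preset, "activity_preset"))
  g <- preset$recovery_gain
  f0 <- 1 - preset$dip_depth
  ifelse(day < 0, 1, g - (g - f0) * exp(-day / preset$recovery_tau))
}

#' Simulate a home-cage locomotion-index trace
#'
#' Generates one cage's minute-resolution locomotion index over
#' `n_days_pre + 1 + n_days_post` days under a 12/12 light/dark schedule
#' (lights on 07:00-19:00). The expected value at minute `t` is
#' `template[bin(t)] * injury_factor(day(t))`; independent Gaussian noise is
#' added and the result clipped to \[0, 1\]. The trace starts at lights-on of
#' day `-n_days_pre`; day 0 is the surgery day.
#'
#' @param preset an [activity_preset()].
#' @param group free-text group tag stored on the trace (e.g.
#'   `"bilateral_free"`).
#' @param seed integer seed; identical `(preset, seed)` give identical traces.
#' @param cage_id cage identifier.
#' @param surgery_day surgery date (`Date` or string).
#' @return an `activity_trace` object: list with `cage_id`, `group`, `start`
#'   (POSIXct, UTC), `period` (seconds), `values`, `lights_on`, `lights_off`,
#'   `surgery_day`, and a `ground_truth` attribute holding the preset, the
#'   seed and the per-day injury factors.
#' @export
simulate_activity <- function(preset, group = "ctr_free", seed,
                              cage_id = paste0("cage_", group, "_", seed),
                              surgery_day = as.Date("2021-06-01")) {
  stopifnot(inherits(preset, "activity_preset"))
  if (missing(seed)) stop("seed must be given", call. = FALSE)
  surgery_day <- as.Date(surgery_day)
  n_days <- preset$n_days_pre + 1L + preset$n_days_post
  days <- seq.int(-preset$n_days_pre, preset$n_days_post)
  fac <- injury_factor(days, preset)
  minute_bin <- rep(0:7, each = 180L)                   # 1440 minutes -> 8 bins
  mu_day <- preset$circadian_template[minute_bin + 1L]  # template by minute
  mu <- rep(fac, each = 1440L) * rep(mu_day, times = n_days)
  values <- with_seed(seed, mu + rnorm(length(mu), 0, preset$noise_sd))
  values <- pmin(pmax(values, 0), 1)
  start <- as.POSIXct(paste(surgery_day - preset$n_days_pre, "07:00:00"),
                      tz = "UTC")
  trace <- structure(
    list(cage_id = cage_id, group = group, start = start, period = 60,
         values = values, lights_on = "07:00", lights_off = "19:00",
         surgery_day = surgery_day),
    class = "activity_trace")
  attr(trace, "ground_truth") <- list(
    preset = preset, seed = seed, day_index = days, injury_factor = fac,
    expected_bin_means = outer(fac, preset$circadian_template))
  trace
}

#' Construct an activity trace from raw values
#'
#' @param values locomotion-index values in \[0, 1\], minute resolution by
#'   default, starting at `lights_on` of the first day.
#' @param cage_id cage identifier.
#' @param surgery_day surgery date.
#' @param n_days_pre number of whole days in `values` preceding the surgery
#'   day.
#' @param period sampling period in seconds.
#' @param group optional group tag.
#' @return an `activity_trace`.
#' @export
activity_trace <- function(values, cage_id = "cage_1",
                           surgery_day = as.Date("2021-06-01"),
                           n_days_pre = 0L, period = 60, group = NA_character_) {
  stop_if_not_finite(values, "values")
  if (any(values < 0 | values > 1)) stop("values must lie in [0, 1]", call. = FALSE)
  spd <- round(86400 / period)
  if (spd * period != 86400) stop("period must divide one day evenly", call. = FALSE)
  if (length(values) %% spd != 0) {
    stop("trace length must be a whole number of days", call. = FALSE)
  }
  surgery_day <- as.Date(surgery_day)
  start <- as.POSIXct(paste(surgery_day - n_days_pre, "07:00:00"), tz = "UTC")
  structure(
    list(cage_id = cage_id, group = group, start = start, period = period,
         values = values, lights_on = "07:00", lights_off = "19:00",
         surgery_day = surgery_day),
    class = "activity_trace")
}

# internal: day index (relative to surgery) and minute-within-activity-day for
# every sample; the activity day runs lights-on to lights-on
trace_index <- function(trace) {
  stopifnot(inherits(trace, "activity_trace"))
  spd <- round(86400 / trace$period)
  n <- length(trace$values)
  sample_day0 <- as.integer(as.Date(trace$start + 0.1) - trace$surgery_day)
  idx <- seq_len(n) - 1L
  day <- sample_day0 + idx %/% spd
  within <- (idx %% spd) * trace$period / 60  # minutes since lights-on
  list(day = day, minute = within, spd = spd)
}

#' Write or read activity traces as CSV
#'
#' Columns: `cage_id`, `timestamp_iso8601`, `activity_index`.
#'
#' @param trace an `activity_trace`.
#' @param path CSV path.
#' @param surgery_day,n_days_pre metadata needed to rebuild the trace on read
#'   (the CSV itself carries only timestamps).
#' @return `read_activity_csv()` returns an `activity_trace`.
#' @export
write_activity_csv <- function(trace, path) {
  stopifnot(inherits(trace, "activity_trace"))
  ts <- trace$start + (seq_along(trace$values) - 1) * trace$period
  df <- data.frame(cage_id = trace$cage_id,
                   timestamp_iso8601 = format(ts, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
                   activity_index = trace$values)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_activity_csv
#' @export
read_activity_csv <- function(path, surgery_day, n_days_pre = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  t0 <- as.POSIXct(df$timestamp_iso8601[1], format = "%Y-%m-%dT%H:%M:%SZ",
                   tz = "UTC")
  surgery_day <- as.Date(surgery_day)
  if (is.null(n_days_pre)) {
    n_days_pre <- as.integer(surgery_day - as.Date(t0 + 0.1))
  }
  period <- as.numeric(difftime(
    as.POSIXct(df$timestamp_iso8601[2], format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    t0, units = "secs"))
  activity_trace(df$activity_index, cage_id = df$cage_id[1],
                 surgery_day = surgery_day, n_days_pre = n_days_pre,
                 period = period)
}
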