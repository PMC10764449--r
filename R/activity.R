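#' Daily light/dark activity means
#'
#' Splits a trace into activity days (lights-on to next lights-on) and
#' averages the light period (lights-on to lights-off, half-open) and the dark
#' period (the 12 h following that day's lights-off) separately. Day 0 is the
#' surgery day; pre-surgery days carry negative indices.
#'
#' @param trace an `activity_trace`.
#' @return data.frame with columns `day_index`, `light_mean`, `dark_mean`.
#' @export
split_day_night <- function(trace) {
  ti <- trace_index(trace)
  if (length(trace$values) < ti$spd) {
    stop("trace shorter than one full day", call. = FALSE)
  }
  is_light <- ti$minute < 720
  light <- tapply(trace$values[is_light], ti$day[is_light], mean)
  dark <- tapply(trace$values[!is_light], ti$day[!is_light], mean)
  data.frame(day_index = as.integer(names(light)),
             light_mean = as.numeric(light),
             dark_mean = as.numeric(dark),
             row.names = NULL)
}

#' Circadian 3-hour bin means
#'
#' Averages each activity day into eight 3-h bins; bin 0 starts at lights-on,
#' bins 4-7 cover the dark period.
#'
#' @param trace an `activity_trace`.
#' @return data.frame with columns `day_index`, `bin` (0-7), `bin_mean`.
#' @export
bin_3h <- function(trace) {
  ti <- trace_index(trace)
  if ((180 * 60) %% trace$period != 0) {
    stop("sampling period does not divide 3 h evenly", call. = FALSE)
  }
  bin <- ti$minute %/% 180
  m <- tapply(trace$values, list(day = ti$day, bin = bin), mean)
  out <- expand.grid(day_index = as.integer(rownames(m)),
                     bin = as.integer(colnames(m)))
  out$bin_mean <- as.numeric(m)
  out[order(out$day_index, out$bin), , drop = FALSE][, c("day_index", "bin", "bin_mean")]
}

#' Aggregate binned activity over named day ranges
#'
#' Averages per-bin activity over named, non-overlapping day ranges (e.g.
#' baseline and post-surgery weeks), as mean and SEM across contributing days.
#'
#' @param binned output of [bin_3h()] (rows from one or more cages may be
#'   concatenated).
#' @param periods named list of integer day-index vectors.
#' @return data.frame with columns `period`, `bin`, `mean`, `sem`, `n_days`.
#' @export
aggregate_bins_by_period <- function(binned, periods) {
  stopifnot(is.list(periods), length(periods) > 0, !is.null(names(periods)))
  all_days <- unlist(periods)
  if (anyDuplicated(all_days)) stop("periods must not overlap", call. = FALSE)
  out <- do.call(rbind, lapply(names(periods), function(p) {
    sub <- binned[binned$day_index %in% periods[[p]], , drop = FALSE]
    if (nrow(sub) == 0) stop("empty period: ", p, call. = FALSE)
    agg <- tapply(sub$bin_mean, sub$bin, function(x) {
      c(mean = mean(x), sem = if (length(x) > 1) sd(x) / sqrt(length(x)) else NA_real_,
        n = length(x))
    })
    df <- do.call(rbind, agg)
    data.frame(period = p, bin = as.integer(names(agg)),
               mean = df[, "mean"], sem = df[, "sem"], n_days = df[, "n"],
               row.names = NULL)
  }))
  out
}

#' Default post-surgery week ranges
#'
#' Baseline is the pre-surgery days; weeks 1-4 are days 1-7, 8-14, 15-21 and
#' 22-27 after surgery.
#'
#' @param n_days_pre number of pre-surgery days available.
#' @return named list of day-index vectors for [aggregate_bins_by_period()].
#' @export
study_periods <- function(n_days_pre = 7) {
  list(baseline = seq.int(-n_days_pre, -1),
       week1 = 1:7, week2 = 8:14, week3 = 15:21, week4 = 22:27)
}

#' Normalize night activity to the pre-surgery baseline
#'
#' Divides each post-surgery night mean (days 0-27, or as far as the trace
#' extends) by the mean night activity of the last `baseline_days` days before
#' surgery.
#'
#' @param summaries output of [split_day_night()] for one cage.
#' @param baseline_days number of pre-surgery days in the baseline (default 3).
#' @param cage_id used in error messages.
#' @return data.frame with columns `day_index`, `normalized_night`,
#'   plus attribute `baseline_mean`; `mode` column is `"baseline"`.
#' @export
normalize_to_baseline <- function(summaries, baseline_days = 3,
                                  cage_id = "cage") {
  base_days <- seq.int(-baseline_days, -1)
  pre <- summaries$dark_mean[summaries$day_index %in% base_days]
  if (length(pre) < baseline_days) {
    stop(sprintf("cage %s: fewer than %d pre-surgery days for baseline",
                 cage_id, baseline_days), call. = FALSE)
  }
  base <- mean(pre)
  if (!is.finite(base) || base <= 0) {
    stop(sprintf("cage %s: baseline night activity is not positive", cage_id),
         call. = FALSE)
  }
  post <- summaries[summaries$day_index >= 0, , drop = FALSE]
  out <- data.frame(day_index = post$day_index,
                    normalized_night = post$dark_mean / base,
                    mode = "baseline")
  attr(out, "baseline_mean") <- base
  out
}

#' Normalize a group's baseline-normalized activity to its control group
#'
#' Each animal's mean baseline-normalized night activity over `days` is
#' divided by the control-group mean of the same quantity. Controls must be
#' matched on wheel condition by the caller.
#'
#' @param group list of [normalize_to_baseline()] outputs, one per animal.
#' @param control same, for the matched control group.
#' @param days day-index window aggregated per animal (default 0-27).
#' @return numeric vector of per-animal ratios (control mean = 1 scale).
#' @export
normalize_to_control <- function(group, control, days = 0:27) {
  stopifnot(length(control) > 0, length(group) > 0)
  per_animal <- function(ns) {
    mean(ns$normalized_night[ns$day_index %in% days])
  }
  ctrl <- vapply(control, per_animal, numeric(1))
  ctrl_mean <- mean(ctrl)
  if (!is.finite(ctrl_mean) || ctrl_mean <= 0) {
    stop("control group mean is not positive", call. = FALSE)
  }
  vapply(group, per_animal, numeric(1)) / ctrl_mean
}
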