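# Exercise-success and exercise-share statistics for the swing-boat protocol.
#
# One hundred percent individual exercise success means at least one detected
# movement after each of the day's rocking stimuli. How individual responses
# are resolved depends on the recording resolution:
#
#  * fine mode (bins no coarser than the inter-stimulus interval): a stimulus
#    is a success if its response window -- from the stimulus to the next one,
#    the last window closing at the end of the session -- contains >= 1 count;
#  * coarse mode (e.g. 1-min bins with 3 stimuli/min): the capped estimator
#    sum_bins min(counts_in_bin, stimuli_in_bin) / total_stimuli. A bin cannot
#    witness more responses than it received stimuli.

# Bin index (1-based) containing each stimulus of one day, or NA outside the
# recording.
stimulus_bins <- function(series, schedule, day) {
  stim <- build_stimulus_schedule(schedule)
  stim <- stim[stim$day == day, , drop = FALSE]
  if (nrow(stim) == 0) return(integer(0))
  # seconds from series start to each stimulus: stimuli are ZT-anchored
  start_zt_s <- zt_hours(series$start, series$schedule) * 3600
  stim_s <- (stim$day - 1) * 86400 + stim$zt_s - start_zt_s
  bin <- floor(stim_s / (series$bin_minutes * 60)) + 1
  bin[bin < 1 | bin > length(series$counts)] <- NA
  as.integer(bin)
}

#' Exercise success for one day
#'
#' Percentage of the day's rocking stimuli that evoked at least one beam
#' crossing, in `[0, 100]`. With bins at least as fine as the inter-stimulus
#' interval each stimulus is scored individually against its response window;
#' with coarser bins the capped estimator
#' `sum(min(counts, stimuli)) / total stimuli` is used. The mode actually used
#' is attached as the `"mode"` attribute of the result. Counts outside the
#' exercise window never affect the result.
#'
#' @param series An [activity_series()] covering the day's exercise window.
#' @param schedule A [stimulus_schedule()].
#' @param day Experiment day (1-based).
#' @return Percent success (numeric scalar) with attribute `mode`
#'   (`"fine"` or `"capped"`); `NA` if the day is not an active exercise day
#'   or the window is fully masked.
#' @examples
#' # 1-min bins, 3 stimuli/min, constant 1 count/min over the 30-min session:
#' # capped estimator gives 30/90 = 33.3%
#' @export
exercise_success <- function(series, schedule, day) {
  stopifnot(inherits(series, "activity_series"),
            inherits(schedule, "stimulus_schedule"))
  if (!(day %in% schedule$active_days)) {
    return(structure(NA_real_, mode = "inactive"))
  }
  bins <- stimulus_bins(series, schedule, day)
  n_stim <- length(bins)
  if (n_stim == 0L) return(structure(NA_real_, mode = "empty"))
  if (anyNA(bins)) {
    stop(sprintf("series does not cover the exercise window of day %d", day))
  }
  interval_s <- 60 / schedule$stimuli_per_minute
  bin_s <- series$bin_minutes * 60
  usable <- series$mask[bins]
  if (!any(usable)) return(structure(NA_real_, mode = "masked"))
  if (bin_s <= interval_s) {
    # fine mode: response window of stimulus i = [stim_i, stim_{i+1}), the
    # last closing at the session end
    window_end_bin <- c(bins[-1], min(length(series$counts),
                                      bins[n_stim] +
                                        ceiling(interval_s / bin_s)))
    hits <- vapply(seq_len(n_stim), function(i) {
      b0 <- bins[i]
      b1 <- max(b0, window_end_bin[i] - 1)
      any(series$counts[b0:b1][series$mask[b0:b1]] > 0)
    }, logical(1))
    pct <- 100 * sum(hits[usable]) / sum(usable)
    structure(pct, mode = "fine")
  } else {
    tab <- table(bins[usable])
    b <- as.integer(names(tab))
    stim_in_bin <- as.integer(tab)
    responded <- pmin(series$counts[b], stim_in_bin)
    pct <- 100 * sum(responded) / sum(stim_in_bin)
    structure(pct, mode = "capped")
  }
}

#' Per-day exercise success across all active days of one fly
#'
#' Fly-days at or after the called death are excluded (consistent with
#' living-only averaging).
#'
#' @inheritParams exercise_success
#' @param death Optional [call_death()] result; computed if `NULL`.
#' @return A data.frame: `fly_id`, `day`, `success`, `mode`.
#' @export
exercise_success_daily <- function(series, schedule, death = NULL) {
  if (is.null(death)) death <- call_death(series)
  death_day <- if (death$event) floor(death$days) + 1 else Inf
  days <- schedule$active_days
  succ <- lapply(days, function(d) {
    if (d >= death_day) return(list(NA_real_, "dead"))
    s <- exercise_success(series, schedule, d)
    list(as.numeric(s), attr(s, "mode"))
  })
  data.frame(fly_id = series$fly_id, day = days,
             success = vapply(succ, function(x) x[[1]], numeric(1)),
             mode = vapply(succ, function(x) x[[2]], character(1)),
             stringsAsFactors = FALSE)
}

#' Group summary of exercise success
#'
#' Per fly, the mean success over its valid active days; the group summary is
#' the median and 25th/75th percentiles of the fly means (the statistics of a
#' Tukey-whisker box plot).
#'
#' @param fly_means Numeric vector of per-fly mean successes (percent), or a
#'   list of data.frames from [exercise_success_daily()] from which the means
#'   are computed.
#' @return A list: `n`, `median`, `q25`, `q75`.
#' @export
group_success_summary <- function(fly_means) {
  if (is.list(fly_means) && !is.numeric(fly_means)) {
    fly_means <- vapply(fly_means, function(df) {
      mean(df$success, na.rm = TRUE)
    }, numeric(1))
  }
  fly_means <- fly_means[!is.na(fly_means)]
  if (length(fly_means) == 0L) stop("no fly with a valid exercise day")
  q <- stats::quantile(fly_means, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  list(n = length(fly_means), median = q[2], q25 = q[1], q75 = q[3])
}

#' Exercise share of overall daily activity
#'
#' Induced locomotor activity quantified relative to the voluntary daily
#' activity of the morning and evening peaks:
#' `100 * exercise-window counts / (morning + evening counts)`, averaged over
#' the active exercise days. Days with zero morning+evening activity are
#' excluded and reported in the `excluded_days` attribute.
#'
#' @param series An [activity_series()].
#' @param schedule A [stimulus_schedule()].
#' @param summaries Optional [summarize_daily()] output for the fly; computed
#'   if `NULL`.
#' @param windows An [episode_windows()].
#' @return Mean percent share across usable active days, with attribute
#'   `excluded_days`.
#' @export
exercise_share <- function(series, schedule, summaries = NULL,
                           windows = episode_windows()) {
  if (is.null(summaries)) summaries <- summarize_daily(series, windows = windows)
  day <- bin_day(series)
  zt <- bin_zt(series)
  w0 <- schedule$start_zt
  w1 <- schedule$start_zt + schedule$duration_min / 60
  in_window <- zt >= w0 & zt < w1
  shares <- numeric(0)
  excluded <- integer(0)
  for (d in schedule$active_days) {
    row <- summaries[summaries$day == d & summaries$alive, , drop = FALSE]
    if (nrow(row) == 0) next
    peaks <- row$activity_morning + row$activity_evening
    ex <- sum(series$counts[in_window & day == d & series$mask])
    if (is.na(peaks) || peaks == 0) {
      excluded <- c(excluded, d)
      next
    }
    shares <- c(shares, 100 * ex / peaks)
  }
  structure(if (length(shares)) mean(shares) else NA_real_,
            excluded_days = excluded)
}
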