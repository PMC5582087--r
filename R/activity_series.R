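# Per-fly activity series: uniformly binned beam-crossing counts with an
# attached light schedule and a per-bin validity mask.

#' Construct an activity series
#'
#' One fly's beam-crossing counts on a uniform time grid. The mask marks bins
#' carrying a valid reading; bins from non-status-1 monitor readings are kept
#' but masked, and downstream scoring treats them as missing.
#'
#' @param counts Non-negative integer vector of beam crossings per bin.
#' @param start `POSIXct` timestamp of the start of the first bin
#'   (timezone-naive local time stored as UTC).
#' @param bin_minutes Bin width in whole minutes.
#' @param schedule A [light_schedule()].
#' @param fly_id Character label for the fly.
#' @param mask Logical vector, `TRUE` where the bin is valid; recycled from a
#'   scalar.
#' @return An object of class `activity_series`.
#' @export
activity_series <- function(counts, start, bin_minutes = 1,
                            schedule = light_schedule(),
                            fly_id = "fly", mask = TRUE) {
  counts <- as.numeric(counts)
  if (any(is.na(counts)) || any(counts < 0)) {
    stop("counts must be non-negative and non-missing (mask invalid bins instead)")
  }
  stopifnot(bin_minutes == as.integer(bin_minutes), bin_minutes >= 1,
            inherits(schedule, "light_schedule"))
  if (length(mask) == 1L) mask <- rep(as.logical(mask), length(counts))
  stopifnot(length(mask) == length(counts))
  start <- as.POSIXct(start, tz = "UTC")
  structure(
    list(fly_id = as.character(fly_id), counts = counts,
         bin_minutes = as.integer(bin_minutes), start = start,
         schedule = schedule, mask = mask),
    class = "activity_series"
  )
}

#' @export
print.activity_series <- function(x, ...) {
  cat(sprintf(
    "activity_series '%s': %d bins x %d min (%.1f days) from %s; %d masked\n",
    x$fly_id, length(x$counts), x$bin_minutes,
    length(x$counts) * x$bin_minutes / 1440,
    format(x$start, "%Y-%m-%d %H:%M"), sum(!x$mask)))
  invisible(x)
}

#' @export
length.activity_series <- function(x) length(x$counts)

#' Timestamps of the bin starts of an activity series
#' @param series An [activity_series()].
#' @return `POSIXct` vector, one per bin.
#' @export
bin_times <- function(series) {
  stopifnot(inherits(series, "activity_series"))
  series$start + (seq_along(series$counts) - 1) * series$bin_minutes * 60
}

#' ZT hours of the bin starts
#' @inheritParams bin_times
#' @return Numeric ZT hours in `[0, 24)`.
#' @export
bin_zt <- function(series) {
  zt_hours(bin_times(series), series$schedule)
}

#' Experiment day index of each bin
#'
#' Days are anchored at the lights-on (ZT0) at or before the series start and
#' numbered from 1. Bins falling in the pre-dawn part of the morning window
#' (ZT20-24) are attached to the following day, keeping the morning episode
#' contiguous within a day.
#'
#' @inheritParams bin_times
#' @param attach_morning If `TRUE` (default), apply the ZT20-24 attachment
#'   rule; if `FALSE`, days run plainly ZT0 to ZT24.
#' @return Integer day index per bin (1-based; can be 0 for pre-dawn bins
#'   before the first full day when `attach_morning = FALSE` never occurs,
#'   and `n_days + 1` for the trailing pre-dawn segment when it does).
#' @export
bin_day <- function(series, attach_morning = TRUE) {
  h <- elapsed_hours_since_anchor(series)
  zt <- h %% 24
  day0 <- floor(h / 24) + 1
  if (attach_morning) day0 <- day0 + (zt >= 20)
  as.integer(day0)
}

# Hours elapsed since the lights-on anchor (ZT0 at or before series start).
elapsed_hours_since_anchor <- function(series) {
  zt0 <- zt_hours(series$start, series$schedule)
  zt0 + (seq_along(series$counts) - 1) * series$bin_minutes / 60
}

#' Rebin an activity series to a coarser bin size
#'
#' Counts are summed over aligned windows, so totals are conserved over any
#' aligned span: a 24-h day at 5-min bins has exactly 288 bins. A coarse bin
#' is masked if any of its constituent bins is masked. A trailing partial
#' window is dropped (with a warning).
#'
#' @param series An [activity_series()].
#' @param target_bin Target bin width in minutes; must be a multiple of the
#'   current bin width.
#' @return An [activity_series()] at the new bin width.
#' @examples
#' s <- activity_series(rep(1, 1440), as.POSIXct("2017-01-01 08:00:00", tz = "UTC"))
#' s5 <- rebin(s, 5)
#' length(s5$counts)      # 288
#' sum(s5$counts)         # 1440, conserved
#' @export
rebin <- function(series, target_bin) {
  stopifnot(inherits(series, "activity_series"))
  if (target_bin %% series$bin_minutes != 0) {
    stop(sprintf("target_bin (%s) must be a multiple of the current bin (%d min)",
                 target_bin, series$bin_minutes))
  }
  k <- as.integer(target_bin / series$bin_minutes)
  if (k == 1L) return(series)
  n <- length(series$counts)
  n_keep <- (n %/% k) * k
  if (n_keep < n) {
    warning(sprintf("dropping %d trailing bins not filling a %d-min window",
                    n - n_keep, as.integer(target_bin)))
  }
  grp <- rep(seq_len(n_keep %/% k), each = k)
  counts <- as.vector(tapply(series$counts[seq_len(n_keep)], grp, sum))
  mask <- as.vector(tapply(series$mask[seq_len(n_keep)], grp, all))
  activity_series(counts, series$start, target_bin, series$schedule,
                  series$fly_id, mask)
}
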