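# Sleep scoring: bout detection from the five-minute inactivity rule, death
# calling from terminal immobility, episode partitioning, and daily summaries.

#' Detect sleep bouts
#'
#' Sleep is scored by the standard fly convention: a maximal run of bins with
#' zero beam crossings lasting at least `threshold_min` minutes (default 5).
#' Bouts lasting at most 60 min are classified as short (fragmented) sleep,
#' bouts longer than 1 h as long (consolidated) sleep.
#'
#' At 1-min bins this is the canonical scoring. On coarser bins (e.g. 5-min
#' display resolution) a single zero bin already spans the 5-min rule, so runs
#' of one or more zero bins qualify; this is an approximation to 1-min scoring
#' and results should be labeled with the bin size used.
#'
#' Masked bins are treated as missing: they interrupt a zero run (sleep is
#' never asserted across unobserved bins).
#'
#' @param series An [activity_series()].
#' @param threshold_min Minimum inactivity duration counted as sleep, minutes.
#' @return A data.frame of class `sleep_bouts` with one row per bout:
#'   `start` (POSIXct), `start_bin`, `n_bins`, `duration_min`, `bout_class`
#'   (`"short"` or `"long"`).
#' @export
detect_sleep_bouts <- function(series, threshold_min = 5) {
  stopifnot(inherits(series, "activity_series"), threshold_min > 0)
  if (all(!series$mask)) {
    warning("all bins are masked; no bouts can be scored")
    return(empty_bouts())
  }
  zero <- series$counts == 0 & series$mask
  r <- rle(zero)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values & (r$lengths * series$bin_minutes >= threshold_min)
  if (!any(keep)) return(empty_bouts())
  sb <- starts[keep]
  nb <- r$lengths[keep]
  dur <- nb * series$bin_minutes
  out <- data.frame(
    start = series$start + (sb - 1) * series$bin_minutes * 60,
    start_bin = sb,
    n_bins = nb,
    duration_min = dur,
    bout_class = ifelse(dur <= 60, "short", "long"),
    stringsAsFactors = FALSE
  )
  class(out) <- c("sleep_bouts", "data.frame")
  out
}

empty_bouts <- function() {
  out <- data.frame(start = as.POSIXct(character(0), tz = "UTC"),
                    start_bin = integer(0), n_bins = integer(0),
                    duration_min = numeric(0), bout_class = character(0),
                    stringsAsFactors = FALSE)
  class(out) <- c("sleep_bouts", "data.frame")
  out
}

# Logical vector: is each bin covered by a bout (optionally of one class)?
bout_cover <- function(series, bouts, class = NULL) {
  cov <- logical(length(series$counts))
  if (nrow(bouts) == 0) return(cov)
  if (!is.null(class)) bouts <- bouts[bouts$bout_class == class, , drop = FALSE]
  for (i in seq_len(nrow(bouts))) {
    cov[bouts$start_bin[i]:(bouts$start_bin[i] + bouts$n_bins[i] - 1)] <- TRUE
  }
  cov
}

#' Call death from terminal immobility
#'
#' A fly is called dead when its terminal run of zero-count bins exceeds
#' `immobility_hours` (default 24 h, strictly greater). The death time is,
#' by default, the end of the last bin with a nonzero count -- the lifespan
#' runs to the last observed movement. A mid-recording immobility run followed
#' by renewed activity is never a death. Flies whose terminal immobility does
#' not exceed the threshold are censored alive at the end of the series.
#'
#' @param series An [activity_series()].
#' @param immobility_hours Immobility duration (hours) beyond which death is
#'   called; the comparison is strict.
#' @param convention `"last_activity"` (default) places the death time at the
#'   end of the last active bin; `"after_immobility"` places it at the point
#'   the immobility criterion is met (last activity + `immobility_hours`).
#' @return An object of class `death_call`: list with `event` (logical),
#'   `time` (POSIXct), `days` (numeric days since series start), and `flag`
#'   (`"ok"`, or `"never_active"` for a series with no counts at all, which is
#'   called dead at the series start and should be reviewed manually).
#' @export
call_death <- function(series, immobility_hours = 24,
                       convention = c("last_activity", "after_immobility")) {
  stopifnot(inherits(series, "activity_series"))
  convention <- match.arg(convention)
  n <- length(series$counts)
  active <- which(series$counts > 0 & series$mask)
  bm <- series$bin_minutes
  if (length(active) == 0L) {
    return(structure(list(event = TRUE, time = series$start, days = 0,
                          flag = "never_active"), class = "death_call"))
  }
  la <- max(active)
  terminal_zero_min <- (n - la) * bm
  if (terminal_zero_min > immobility_hours * 60) {
    t_death <- series$start + la * bm * 60
    if (convention == "after_immobility") {
      t_death <- t_death + immobility_hours * 3600
    }
    days <- as.numeric(difftime(t_death, series$start, units = "days"))
    structure(list(event = TRUE, time = t_death, days = days, flag = "ok"),
              class = "death_call")
  } else {
    structure(list(event = FALSE, time = series$start + n * bm * 60,
                   days = n * bm / 1440, flag = "ok"),
              class = "death_call")
  }
}

#' @export
print.death_call <- function(x, ...) {
  if (x$event) {
    cat(sprintf("death at day %.2f (%s)%s\n", x$days, format(x$time),
                if (x$flag != "ok") paste0(" [", x$flag, "]") else ""))
  } else {
    cat(sprintf("censored alive at day %.2f\n", x$days))
  }
  invisible(x)
}

#' Partition a day's activity and sleep into behavioral episodes
#'
#' Attributes each bin's activity counts and sleep minutes to its experiment
#' day and behavioral episode (night, morning, siesta, evening). Sleep is
#' attributed minute-by-minute from the bout cover, so a bout spanning a
#' window boundary is split pro-rata by overlap and per-day episode sums
#' reconcile with daily totals. Masked bins contribute to neither.
#'
#' @param series An [activity_series()].
#' @param bouts Output of [detect_sleep_bouts()] for the same series.
#' @param windows An [episode_windows()].
#' @return A data.frame with one row per (day, episode): columns `day`,
#'   `episode`, `activity`, `sleep_min`, `valid_min`.
#' @export
partition_episodes <- function(series, bouts, windows = episode_windows()) {
  stopifnot(inherits(series, "activity_series"))
  day <- bin_day(series)
  ep <- episode_of(bin_zt(series), windows)
  sleeping <- bout_cover(series, bouts)
  bm <- series$bin_minutes
  ok <- series$mask
  key <- interaction(day, ep, drop = TRUE)
  agg <- function(v) as.vector(tapply(v, key, sum))
  lev <- levels(key)
  parts <- strsplit(lev, ".", fixed = TRUE)
  out <- data.frame(
    day = as.integer(vapply(parts, `[`, "", 1)),
    episode = vapply(parts, `[`, "", 2),
    activity = agg(series$counts * ok),
    sleep_min = agg(sleeping * ok * bm),
    valid_min = agg(ok * bm),
    stringsAsFactors = FALSE
  )
  out[order(out$day, match(out$episode, windows$episode)), , drop = FALSE]
}

#' Per-day behavioral summaries for one fly
#'
#' One row per experiment day covered by the recording: total and per-episode
#' activity counts and sleep minutes, short-term (fragmented, bouts <= 60 min)
#' and long-term (bouts > 1 h) sleep minutes, and an alive flag. Days at or
#' after the called death carry `alive = FALSE` and no behavioral values.
#' Days are anchored at lights-on; bins in ZT20-24 attach to the following
#' day's morning (see [bin_day()]).
#'
#' @param series An [activity_series()].
#' @param bouts Sleep bouts; computed with [detect_sleep_bouts()] if `NULL`.
#' @param death A [call_death()] result; computed if `NULL`.
#' @param windows An [episode_windows()].
#' @param threshold_min Sleep threshold passed to [detect_sleep_bouts()] when
#'   `bouts` is `NULL`.
#' @param min_coverage Minimum fraction of a day's 1440 minutes that must be
#'   present (recorded and unmasked) for the day to be summarised. The default
#'   0.8 retains the first experiment day, which under the morning-attachment
#'   convention lacks its pre-lights-on segment, while dropping trailing
#'   fragments.
#' @return A data.frame of class `daily_summary`, one row per day: `fly_id`,
#'   `day`, `alive`, `activity`, `sleep`, `sleep_short`, `sleep_long`,
#'   `activity_<episode>` and `sleep_<episode>` for the four episodes, and
#'   `valid_min`.
#' @export
summarize_daily <- function(series, bouts = NULL, death = NULL,
                            windows = episode_windows(), threshold_min = 5,
                            min_coverage = 0.8) {
  stopifnot(inherits(series, "activity_series"))
  if (is.null(bouts)) bouts <- detect_sleep_bouts(series, threshold_min)
  if (is.null(death)) death <- call_death(series)
  day <- bin_day(series)
  ep <- episode_of(bin_zt(series), windows)
  bm <- series$bin_minutes
  ok <- series$mask
  sleeping <- bout_cover(series, bouts)
  sleep_short <- bout_cover(series, bouts, "short")
  sleep_long <- bout_cover(series, bouts, "long")

  death_day <- if (death$event) {
    # day index containing the death time (end of last active bin)
    bin_at <- min(max(1L, ceiling(death$days * 1440 / bm)), length(series$counts))
    bin_day(series)[bin_at]
  } else {
    Inf
  }

  days <- sort(unique(day))
  rows <- lapply(days, function(d) {
    sel <- day == d
    valid_min <- sum(ok[sel]) * bm
    if (valid_min < min_coverage * 1440) return(NULL)
    alive <- d < death_day
    row <- data.frame(fly_id = series$fly_id, day = d, alive = alive,
                      activity = NA_real_, sleep = NA_real_,
                      sleep_short = NA_real_, sleep_long = NA_real_,
                      stringsAsFactors = FALSE)
    for (e in windows$episode) {
      row[[paste0("activity_", e)]] <- NA_real_
      row[[paste0("sleep_", e)]] <- NA_real_
    }
    row$valid_min <- valid_min
    if (alive) {
      row$activity <- sum(series$counts[sel & ok])
      row$sleep <- sum(sleeping[sel & ok]) * bm
      row$sleep_short <- sum(sleep_short[sel & ok]) * bm
      row$sleep_long <- sum(sleep_long[sel & ok]) * bm
      for (e in windows$episode) {
        sel_e <- sel & ok & ep == e
        row[[paste0("activity_", e)]] <- sum(series$counts[sel_e])
        row[[paste0("sleep_", e)]] <- sum(sleeping[sel_e]) * bm
      }
    }
    row
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(fly_id = character(0), day = integer(0),
                      alive = logical(0))
  }
  class(out) <- c("daily_summary", "data.frame")
  out
}
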