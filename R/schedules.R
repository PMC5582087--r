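# Light schedules, Zeitgeber time, episode windows, and the rocking stimulus
# schedule.

#' Define a light:dark entrainment schedule
#'
#' A light schedule anchors Zeitgeber time (ZT): ZT0 is lights-on, ZT12 is
#' lights-off under the default 12:12 h light:dark (LD12:12) cycle.
#'
#' @param lights_on Clock time of lights-on in decimal hours (default 8,
#'   i.e. 08:00).
#' @param hours_light,hours_dark Photoperiod in hours; must sum to 24.
#' @return An object of class `light_schedule`.
#' @examples
#' sched <- light_schedule(lights_on = 8)
#' zt_hours(as.POSIXct("2017-01-01 15:00:00", tz = "UTC"), sched)  # ZT7
#' @export
light_schedule <- function(lights_on = 8, hours_light = 12, hours_dark = 12) {
  stopifnot(is.numeric(lights_on), lights_on >= 0, lights_on < 24)
  if (hours_light + hours_dark != 24) {
    stop("hours_light + hours_dark must equal 24")
  }
  structure(
    list(lights_on = lights_on, hours_light = hours_light,
         hours_dark = hours_dark),
    class = "light_schedule"
  )
}

#' @export
print.light_schedule <- function(x, ...) {
  cat(sprintf("LD%g:%g light schedule, lights on at %02d:%02d (ZT0)\n",
              x$hours_light, x$hours_dark,
              floor(x$lights_on), round((x$lights_on %% 1) * 60)))
  invisible(x)
}

#' Convert clock timestamps to Zeitgeber time
#'
#' @param times A `POSIXct` vector (timezone-naive local time, stored as UTC).
#' @param schedule A [light_schedule()].
#' @return Numeric vector of ZT hours in `[0, 24)`.
#' @export
zt_hours <- function(times, schedule) {
  stopifnot(inherits(schedule, "light_schedule"))
  lt <- as.POSIXlt(times, tz = "UTC")
  clock <- lt$hour + lt$min / 60 + lt$sec / 3600
  (clock - schedule$lights_on) %% 24
}

#' Whether timestamps fall in the light phase
#'
#' @inheritParams zt_hours
#' @return Integer vector, 1 during lights-on, 0 during darkness.
#' @export
light_flag <- function(times, schedule) {
  as.integer(zt_hours(times, schedule) < schedule$hours_light)
}

#' Daily behavioral episode windows
#'
#' The day is partitioned into four clock-time windows used to summarise
#' sleep and activity: night (22:00-04:00), morning (04:00-12:00), siesta
#' (12:00-16:00) and evening (16:00-22:00). With lights-on at 08:00 these
#' correspond to ZT14-20, ZT20-4, ZT4-8 and ZT8-14. The windows are disjoint
#' and tile 24 h (6 + 8 + 4 + 6 hours).
#'
#' @param schedule A [light_schedule()]; windows are stored in ZT so a
#'   different lights-on shifts the clock times, not the ZT layout.
#' @return An object of class `episode_windows`: a data.frame with columns
#'   `episode`, `zt_start`, `zt_end` (hours; end exclusive, morning wraps
#'   through ZT24).
#' @export
episode_windows <- function(schedule = light_schedule()) {
  w <- data.frame(
    episode  = c("night", "morning", "siesta", "evening"),
    zt_start = c(14, 20, 4, 8),
    zt_end   = c(20, 28, 8, 14),   # morning wraps: ZT20 -> ZT28 (= ZT4)
    stringsAsFactors = FALSE
  )
  spans <- w$zt_end - w$zt_start
  stopifnot(sum(spans) == 24)
  structure(w, class = c("episode_windows", "data.frame"))
}

#' Label ZT hours with their behavioral episode
#'
#' @param zt Numeric vector of ZT hours in `[0, 24)`.
#' @param windows An [episode_windows()] object.
#' @return Character vector of episode labels.
#' @export
episode_of <- function(zt, windows = episode_windows()) {
  out <- character(length(zt))
  for (i in seq_len(nrow(windows))) {
    lo <- windows$zt_start[i]
    hi <- windows$zt_end[i]
    if (hi <= 24) {
      sel <- zt >= lo & zt < hi
    } else {
      sel <- zt >= lo | zt < (hi - 24)
    }
    out[sel] <- windows$episode[i]
  }
  out
}

#' Define the swing-boat stimulation protocol
#'
#' The rocking protocol tilts the fly tubes in repeated cycles during a daily
#' exercise window. Defaults follow a 30-min session starting at ZT7 with
#' three tilts per minute (90 stimuli per day), displacement 30 degrees at
#' 30 degrees/s with a 17 s pause between motions, applied on days 1-12.
#'
#' @param start_zt Session start in ZT hours.
#' @param duration_min Session length in minutes.
#' @param stimuli_per_minute Tilt rate (stimuli per minute).
#' @param displacement_deg Tilt displacement angle (degrees).
#' @param angular_velocity_deg_s Tilt angular velocity (degrees per second).
#' @param pause_s Pause between successive motions (seconds).
#' @param active_days Integer vector of experiment days (1-based) on which
#'   the protocol runs.
#' @return An object of class `stimulus_schedule`.
#' @examples
#' sched <- stimulus_schedule()
#' sched$stimuli_per_day  # 90
#' @export
stimulus_schedule <- function(start_zt = 7, duration_min = 30,
                              stimuli_per_minute = 3,
                              displacement_deg = 30,
                              angular_velocity_deg_s = 30,
                              pause_s = 17,
                              active_days = 1:12) {
  stopifnot(duration_min >= 0, stimuli_per_minute >= 0)
  n_stim <- duration_min * stimuli_per_minute
  if (abs(n_stim - round(n_stim)) > 1e-9) {
    stop("duration_min * stimuli_per_minute must be an integer stimulus count")
  }
  structure(
    list(start_zt = start_zt, duration_min = duration_min,
         stimuli_per_minute = stimuli_per_minute,
         displacement_deg = displacement_deg,
         angular_velocity_deg_s = angular_velocity_deg_s,
         pause_s = pause_s, active_days = as.integer(active_days),
         stimuli_per_day = as.integer(round(n_stim))),
    class = "stimulus_schedule"
  )
}

#' @export
print.stimulus_schedule <- function(x, ...) {
  cat(sprintf(
    "swing-boat schedule: %d min from ZT%g, %g stimuli/min (%d/day), days %s\n",
    x$duration_min, x$start_zt, x$stimuli_per_minute, x$stimuli_per_day,
    if (length(x$active_days)) paste0(min(x$active_days), "-", max(x$active_days))
    else "(none)"))
  invisible(x)
}

#' Expand a stimulus schedule into explicit per-day stimulus times
#'
#' Stimuli are evenly spaced at `60 / stimuli_per_minute` second intervals
#' from the session start, so all stimulus times fall within
#' `[start_zt, start_zt + duration_min/60)`.
#'
#' @param schedule A [stimulus_schedule()].
#' @return A data.frame with columns `day` (experiment day) and `zt_s`
#'   (stimulus time in seconds after ZT0 of that day), ordered by day then
#'   time; one row per stimulus.
#' @export
build_stimulus_schedule <- function(schedule) {
  stopifnot(inherits(schedule, "stimulus_schedule"))
  n <- schedule$stimuli_per_day
  if (n == 0L || length(schedule$active_days) == 0L) {
    return(data.frame(day = integer(0), zt_s = numeric(0)))
  }
  interval_s <- 60 / schedule$stimuli_per_minute
  offsets <- (seq_len(n) - 1) * interval_s
  out <- data.frame(
    day  = rep(schedule$active_days, each = n),
    zt_s = rep(schedule$start_zt * 3600 + offsets,
               times = length(schedule$active_days))
  )
  out[order(out$day, out$zt_s), , drop = FALSE]
}
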