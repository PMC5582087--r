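# Stochastic simulator of per-minute DAM beam-crossing series.
#
# Each fly is a two-state (wake/sleep) alternating-bout process on a 1-min
# grid. Exit probabilities are modulated by a circadian sleep-drive template
# (high at night and during the siesta, low around the activity peaks) and by
# a fragmentation factor that multiplies both bout-exit rates, shortening
# bouts without changing the equilibrium sleep fraction. Wake minutes emit
# Poisson counts from a circadian intensity template (baseline + morning and
# evening Gaussian peaks, suppressed in the siesta and at night) with a
# multiplicative per-day age trend; sleep minutes emit zero. Arrhythmic
# nocturnal wake bursts are inserted at a planted per-night rate. On exercise
# days the stimulation window overrides spontaneous behavior: each rocking
# stimulus independently elicits one count (recorded in the minute containing
# the stimulus) with probability p_resp. Death times are log-normal
# (parameterized by the median); all counts after death are zero.

#' Define a genotype/treatment activity profile
#'
#' @param label Profile name.
#' @param baseline_rate Baseline wake activity intensity (counts/min).
#' @param morning_peak,evening_peak Lists `list(height, center_zt, width_h)`
#'   describing Gaussian activity peaks (counts/min, ZT hours, hours).
#' @param siesta_factor,night_factor Multipliers on the baseline intensity in
#'   the siesta (ZT4-8) and the dark phase (ZT12-24).
#' @param mean_wake_min,mean_sleep_min Mean wake and sleep bout durations
#'   (minutes) before circadian modulation.
#' @param fragmentation Factor >= 0 multiplying both bout-exit rates; values
#'   above 1 shorten all bouts (more fragmented sleep) without changing the
#'   equilibrium sleep fraction.
#' @param night_sleep_drive,siesta_sleep_drive,peak_sleep_drive Sleep-drive
#'   multipliers at night (ZT12-24), in the siesta (ZT4-8) and around the
#'   activity peaks (ZT0-2, ZT10-12); elsewhere the drive is 1.
#' @param spike_rate Expected arrhythmic nocturnal wake bursts per night.
#' @param spike_intensity Mean counts/min during a burst (at least 1 count is
#'   emitted).
#' @param p_resp Probability that a single rocking stimulus elicits a count.
#' @param age_slope Per-day multiplicative trend on wake intensity
#'   (`intensity * max(0, 1 + age_slope * (day - 1))`).
#' @param mortality_median_days,mortality_median_days_exercise Median of the
#'   log-normal death-time distribution (days) for stationary and exercising
#'   flies.
#' @param mortality_shape Log-scale SD of the death-time distribution.
#' @return An object of class `genotype_profile`.
#' @export
genotype_profile <- function(label,
                             baseline_rate = 1.2,
                             morning_peak = list(height = 4, center_zt = 0.5,
                                                 width_h = 0.8),
                             evening_peak = list(height = 5, center_zt = 11.5,
                                                 width_h = 1.0),
                             siesta_factor = 0.25,
                             night_factor = 0.15,
                             mean_wake_min = 20,
                             mean_sleep_min = 40,
                             fragmentation = 1,
                             night_sleep_drive = 3,
                             siesta_sleep_drive = 2.5,
                             peak_sleep_drive = 0.4,
                             spike_rate = 0.5,
                             spike_intensity = 4,
                             p_resp = 0.4,
                             age_slope = -0.01,
                             mortality_median_days = 38,
                             mortality_median_days_exercise = mortality_median_days,
                             mortality_shape = 0.2) {
  stopifnot(p_resp >= 0, p_resp <= 1, fragmentation >= 0,
            baseline_rate >= 0, spike_rate >= 0,
            mean_wake_min > 0, mean_sleep_min > 0,
            mortality_median_days > 0, mortality_shape >= 0)
  structure(as.list(environment()), class = "genotype_profile")
}

#' @export
print.genotype_profile <- function(x, ...) {
  cat(sprintf(
    "genotype_profile '%s': p_resp = %.4f, fragmentation = %.2f, median survival = %.1f/%.1f d (stationary/exercise)\n",
    x$label, x$p_resp, x$fragmentation, x$mortality_median_days,
    x$mortality_median_days_exercise))
  invisible(x)
}

# Gaussian bump in ZT, wrapping around 24 h.
zt_gauss <- function(zt, center, width, height) {
  d <- pmin(abs(zt - center), 24 - abs(zt - center))
  height * exp(-0.5 * (d / width)^2)
}

# Per-minute wake intensity template over one day (1440 values, ZT-aligned).
intensity_template <- function(profile) {
  zt <- (seq_len(1440) - 1) / 60
  base <- rep(profile$baseline_rate, 1440)
  base[zt >= 4 & zt < 8] <- profile$baseline_rate * profile$siesta_factor
  base[zt >= 12] <- profile$baseline_rate * profile$night_factor
  base +
    zt_gauss(zt, profile$morning_peak$center_zt, profile$morning_peak$width_h,
             profile$morning_peak$height) +
    zt_gauss(zt, profile$evening_peak$center_zt, profile$evening_peak$width_h,
             profile$evening_peak$height)
}

# Per-minute sleep-drive template over one day.
sleep_drive_template <- function(profile) {
  zt <- (seq_len(1440) - 1) / 60
  s <- rep(1, 1440)
  s[zt >= 12] <- profile$night_sleep_drive
  s[zt >= 4 & zt < 8] <- profile$siesta_sleep_drive
  s[(zt >= 0 & zt < 2) | (zt >= 10 & zt < 12)] <- profile$peak_sleep_drive
  s
}

#' The four bundled calibration profiles
#'
#' Profiles loosely calibrated to the study conditions of a swing-boat
#' experiment on an amyloid-beta fly model and its controls: a wild-type-like
#' strain, a low-responding driver-like strain, a reporter-like strain, and an
#' AD-like strain with high stimulus responsiveness, frequent nocturnal
#' activity spikes, elevated sleep fragmentation, reduced night sleep drive
#' and short median survival. Per-stimulus response probabilities are set to
#' the reported group medians (0.3862, 0.0944, 0.4176, 0.4814) and median
#' survivals to the reported stationary/exercising values.
#'
#' @return A named list of four [genotype_profile()] objects:
#'   `wild_type`, `driver`, `reporter`, `ad`.
#' @export
default_profiles <- function() {
  list(
    wild_type = genotype_profile(
      "wild_type", p_resp = 0.3862,
      mortality_median_days = 40.0, mortality_median_days_exercise = 38.0),
    driver = genotype_profile(
      "driver", p_resp = 0.0944,
      evening_peak = list(height = 6.5, center_zt = 11.5, width_h = 1.0),
      mortality_median_days = 27.0, mortality_median_days_exercise = 31.0),
    reporter = genotype_profile(
      "reporter", p_resp = 0.4176,
      mortality_median_days = 35.0, mortality_median_days_exercise = 34.0),
    ad = genotype_profile(
      "ad", p_resp = 0.4814,
      baseline_rate = 1.6, fragmentation = 2.2,
      night_sleep_drive = 1.8, spike_rate = 8, spike_intensity = 4,
      age_slope = -0.03,
      mortality_median_days = 21.5, mortality_median_days_exercise = 28.5)
  )
}

#' Simulation configuration
#'
#' @param groups A list of group descriptions, each a list with elements
#'   `profile` (a [genotype_profile()]), `exercising` (logical) and `n`
#'   (flies, default 32, at most 32 per monitor).
#' @param days Recording length in days.
#' @param light A [light_schedule()].
#' @param stimulus A [stimulus_schedule()].
#' @param seed Integer master seed; together with the per-fly substream rule
#'   it fully determines the output, and adding flies or groups never
#'   reshuffles the series of existing ones.
#' @param start Timestamp of the first minute (defaults to lights-on of an
#'   arbitrary reference date).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(groups, days = 20, light = light_schedule(),
                       stimulus = stimulus_schedule(), seed = 1,
                       start = NULL) {
  stopifnot(is.list(groups), length(groups) >= 1)
  for (g in groups) {
    stopifnot(inherits(g$profile, "genotype_profile"))
    if (is.null(g$n)) g$n <- 32L
    stopifnot(g$n >= 1, g$n <= 32)
  }
  if (is.null(start)) {
    start <- as.POSIXct(sprintf("2017-01-01 %02d:%02d:00",
                                floor(light$lights_on),
                                round((light$lights_on %% 1) * 60)),
                        tz = "UTC")
  }
  structure(list(groups = groups, days = as.integer(days), light = light,
                 stimulus = stimulus, seed = as.integer(seed),
                 start = as.POSIXct(start, tz = "UTC")),
            class = "sim_config")
}

# Deterministic per-fly seed substream (kept below 2^31).
fly_seed <- function(master_seed, group_index, fly_index) {
  (as.numeric(master_seed) * 7919 + group_index * 1299709 +
     fly_index * 104729) %% 2147483647
}

#' Simulate one fly
#'
#' @param profile A [genotype_profile()].
#' @param exercising Logical; whether the fly undergoes the rocking protocol.
#' @param config A [sim_config()] (its `groups` entry is ignored here).
#' @param seed Integer seed for this fly's stream.
#' @param fly_id Label.
#' @return A list: `series` (the per-minute [activity_series()]) and `truth`
#'   (list with `death_day` -- `NA` if the fly outlives the recording --,
#'   `p_resp`, and `bouts`, the emitted-inactivity bout log as a data.frame
#'   `start_min`, `duration_min` of all maximal zero runs before death).
#' @export
simulate_fly <- function(profile, exercising, config, seed = config$seed,
                         fly_id = profile$label) {
  stopifnot(inherits(profile, "genotype_profile"),
            inherits(config, "sim_config"))
  n <- config$days * 1440L
  set.seed(seed)

  intensity <- rep(intensity_template(profile), length.out = n)
  drive <- rep(sleep_drive_template(profile), length.out = n)
  day <- (seq_len(n) - 1L) %/% 1440L + 1L
  zt_min <- (seq_len(n) - 1L) %% 1440L
  age_mod <- pmax(0, 1 + profile$age_slope * (day - 1))

  # 1) death time
  med <- if (exercising) profile$mortality_median_days_exercise
         else profile$mortality_median_days
  death_day_true <- stats::rlnorm(1, meanlog = log(med),
                                  sdlog = profile$mortality_shape)

  # 2) wake/sleep state chain (exit probabilities per minute)
  q_ws <- pmin(1, profile$fragmentation * drive / profile$mean_wake_min)
  q_sw <- pmin(1, profile$fragmentation / (profile$mean_sleep_min * drive))
  u <- stats::runif(n)
  awake <- logical(n)
  a <- TRUE
  for (i in seq_len(n)) {
    a <- if (a) u[i] >= q_ws[i] else u[i] < q_sw[i]
    awake[i] <- a
  }

  # 3) wake-minute counts
  counts <- integer(n)
  counts[awake] <- stats::rpois(sum(awake), intensity[awake] * age_mod[awake])

  # 4) arrhythmic nocturnal wake bursts
  if (profile$spike_rate > 0) {
    night_of_day <- split(which(zt_min >= 720), day[zt_min >= 720])
    for (mins in night_of_day) {
      n_sp <- stats::rpois(1, profile$spike_rate)
      if (n_sp == 0) next
      starts <- sample(mins, n_sp, replace = TRUE)
      for (s0 in starts) {
        len <- sample(2:4, 1)
        idx <- s0:min(s0 + len - 1, n)
        counts[idx] <- pmax(1L, stats::rpois(length(idx),
                                             profile$spike_intensity))
      }
    }
  }

  # 5) exercise responses: the stimulation window overrides spontaneous
  # behavior on active days
  if (exercising && config$stimulus$stimuli_per_day > 0) {
    stim <- build_stimulus_schedule(config$stimulus)
    stim <- stim[stim$day <= config$days, , drop = FALSE]
    if (nrow(stim)) {
      w0 <- config$stimulus$start_zt * 60
      w1 <- w0 + config$stimulus$duration_min
      in_window <- zt_min >= w0 & zt_min < w1 &
        day %in% config$stimulus$active_days
      counts[in_window] <- 0L
      stim_minute <- (stim$day - 1L) * 1440L + floor(stim$zt_s / 60) + 1L
      responded <- stats::runif(nrow(stim)) < profile$p_resp
      hit <- table(stim_minute[responded])
      idx <- as.integer(names(hit))
      counts[idx] <- counts[idx] + as.integer(hit)
    }
  }

  # 6) death: all counts are zero forever after
  death_min <- floor(death_day_true * 1440)
  if (death_min < n) counts[(death_min + 1L):n] <- 0L

  series <- activity_series(counts, config$start, 1, config$light, fly_id)

  pre <- seq_len(min(death_min, n))
  r <- rle(counts[pre] == 0L)
  ends <- cumsum(r$lengths)
  bouts <- data.frame(
    start_min = (ends - r$lengths + 1)[r$values],
    duration_min = r$lengths[r$values]
  )
  list(series = series,
       truth = list(
         death_day = if (death_min < n) death_day_true else NA_real_,
         p_resp = profile$p_resp,
         bouts = bouts))
}

#' Simulate a whole experiment and write DAM monitor files
#'
#' Simulates every group of the configuration, writes one monitor file per
#' group (32 channels; unused channels carry zeros and are listed in the truth
#' table as empty), and writes a truth table CSV with the planted parameters.
#'
#' @param config A [sim_config()].
#' @param out_dir Directory for the monitor files and truth table; created if
#'   needed. If `NULL`, no files are written.
#' @return A list: `series` (list of [activity_series()]), `truth`
#'   (data.frame: `fly_id`, `group`, `exercising`, `monitor`, `channel`,
#'   `death_day`, `p_resp`, `fragmentation`, `mortality_median`), `files`
#'   (character vector of written monitor files), `truth_file`.
#' @export
simulate_experiment <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  all_series <- list()
  truth_rows <- list()
  files <- character(0)
  truth_file <- NULL
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  n_min <- config$days * 1440L
  ts <- config$start + (seq_len(n_min) - 1) * 60
  light <- light_flag(ts, config$light)
  for (gi in seq_along(config$groups)) {
    g <- config$groups[[gi]]
    n_fly <- if (is.null(g$n)) 32L else as.integer(g$n)
    monitor_id <- sprintf("M%02d_%s_%s", gi, g$profile$label,
                          if (isTRUE(g$exercising)) "ex" else "stat")
    counts <- matrix(0L, n_min, 32)
    for (fi in seq_len(n_fly)) {
      fid <- sprintf("%s_ch%02d", monitor_id, fi)
      sim <- simulate_fly(g$profile, isTRUE(g$exercising), config,
                          seed = fly_seed(config$seed, gi, fi), fly_id = fid)
      counts[, fi] <- sim$series$counts
      all_series[[fid]] <- sim$series
      truth_rows[[fid]] <- data.frame(
        fly_id = fid, group = g$profile$label,
        exercising = isTRUE(g$exercising), monitor = monitor_id,
        channel = fi, death_day = sim$truth$death_day,
        p_resp = g$profile$p_resp,
        fragmentation = g$profile$fragmentation,
        mortality_median = if (isTRUE(g$exercising))
          g$profile$mortality_median_days_exercise
        else g$profile$mortality_median_days,
        stringsAsFactors = FALSE)
    }
    if (!is.null(out_dir)) {
      tab <- monitor_table(ts, counts, status = 1L, monitor_id = monitor_id,
                           light = light)
      f <- file.path(out_dir, paste0(monitor_id, ".txt"))
      write_monitor_file(tab, f)
      files <- c(files, f)
    }
  }
  truth <- do.call(rbind, truth_rows)
  rownames(truth) <- NULL
  if (!is.null(out_dir)) {
    truth_file <- file.path(out_dir, "truth.csv")
    utils::write.csv(truth, truth_file, row.names = FALSE)
  }
  list(series = all_series, truth = truth, files = files,
       truth_file = truth_file)
}
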