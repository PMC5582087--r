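# Shared fixtures and independent oracles for the test suite.

T0 <- as.POSIXct("2017-01-01 08:00:00", tz = "UTC")  # lights-on, ZT0

# A minimal series: counts at 1-min bins starting at lights-on.
make_series <- function(counts, bin_minutes = 1, start = T0, mask = TRUE,
                        fly_id = "test") {
  activity_series(counts, start, bin_minutes, light_schedule(), fly_id, mask)
}

# Brute-force maximal-zero-run scan: the independent oracle for sleep-bout
# detection. Returns data.frame(start_bin, n_bins) of all maximal zero runs
# meeting the threshold.
brute_force_bouts <- function(counts, bin_minutes = 1, threshold_min = 5) {
  n <- length(counts)
  starts <- integer(0); lens <- integer(0)
  i <- 1
  while (i <= n) {
    if (counts[i] == 0) {
      j <- i
      while (j < n && counts[j + 1] == 0) j <- j + 1
      if ((j - i + 1) * bin_minutes >= threshold_min) {
        starts <- c(starts, i); lens <- c(lens, j - i + 1)
      }
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  data.frame(start_bin = starts, n_bins = lens)
}

# Brute-force death rule applied bin by bin: dead iff the zero run containing
# the final bin is terminal and longer than the immobility threshold.
brute_force_death <- function(counts, bin_minutes = 1, immobility_hours = 24) {
  n <- length(counts)
  active <- which(counts > 0)
  if (length(active) == 0) return(list(event = TRUE, last_active = 0))
  la <- max(active)
  list(event = (n - la) * bin_minutes > immobility_hours * 60,
       last_active = la)
}

# Small DAM monitor fixture: n readings, 32 channels.
make_monitor <- function(n = 10, counts = NULL, status = 1L, start = T0,
                         interval_min = 1) {
  ts <- start + (seq_len(n) - 1) * interval_min * 60
  if (is.null(counts)) {
    counts <- matrix(rpois(n * 32, 2), n, 32)
  }
  monitor_table(ts, counts, status = status, monitor_id = "Mtest",
                light = light_flag(ts, light_schedule()))
}
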