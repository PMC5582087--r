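# Sleep scoring: rebinning, bout detection, death calling, episode
# partitioning, and daily summaries.

test_that("rebinning 1440 one-minute bins of value 1 gives 288 five-minute bins of 5", {
  s <- make_series(rep(1, 1440))
  s5 <- rebin(s, 5)
  expect_equal(length(s5$counts), 288L)
  expect_true(all(s5$counts == 5))
  expect_equal(sum(s5$counts), sum(s$counts))
})

test_that("rebinning to the same bin is the identity and conserves random totals", {
  set.seed(10)
  for (rep in 1:20) {
    counts <- rpois(1440, 2)
    s <- make_series(counts)
    expect_identical(rebin(s, 1), s)
    s5 <- rebin(s, 5)
    expect_equal(sum(s5$counts), sum(counts))
    # aligned-window conservation: any whole hour
    h <- sample(0:23, 1)
    expect_equal(sum(s5$counts[(h * 12 + 1):(h * 12 + 12)]),
                 sum(counts[(h * 60 + 1):(h * 60 + 60)]))
  }
  expect_error(rebin(make_series(rep(0, 10)), 3.5), "multiple")
})

test_that("an all-zero day is one long bout; a 4-min lull is no bout", {
  b <- detect_sleep_bouts(make_series(rep(0, 1440)))
  expect_equal(nrow(b), 1L)
  expect_equal(b$duration_min, 1440)
  expect_equal(b$bout_class, "long")

  counts <- c(1, rep(0, 4), 1, rep(1, 10))
  expect_equal(nrow(detect_sleep_bouts(make_series(counts))), 0L)
  # exactly 5 zero minutes qualifies
  counts <- c(1, rep(0, 5), 1)
  b <- detect_sleep_bouts(make_series(counts))
  expect_equal(b$duration_min, 5)
  expect_equal(b$start_bin, 2L)
})

test_that("a 60-min bout is short, a 61-min bout is long", {
  counts <- c(1, rep(0, 60), 1, rep(0, 61), 1)
  b <- detect_sleep_bouts(make_series(counts))
  expect_equal(b$bout_class, c("short", "long"))
})

test_that("bout detection equals the brute-force maximal-zero-run oracle", {
  set.seed(42)
  for (rep in 1:1000) {
    counts <- rbinom(200, 1, runif(1, 0.2, 0.8)) * rpois(200, 2)
    got <- detect_sleep_bouts(make_series(counts))
    want <- brute_force_bouts(counts)
    expect_equal(got$start_bin, want$start_bin)
    expect_equal(got$n_bins, want$n_bins)
  }
})

test_that("raising the sleep threshold never increases total sleep", {
  set.seed(7)
  for (rep in 1:50) {
    counts <- rbinom(500, 1, 0.5) * rpois(500, 1)
    s <- make_series(counts)
    sleep5 <- sum(detect_sleep_bouts(s, 5)$duration_min)
    sleep10 <- sum(detect_sleep_bouts(s, 10)$duration_min)
    expect_lte(sleep10, sleep5)
  }
})

test_that("masked bins interrupt zero runs and all-masked series warn", {
  counts <- rep(0, 20)
  mask <- rep(TRUE, 20); mask[10] <- FALSE
  b <- detect_sleep_bouts(make_series(counts, mask = mask))
  expect_equal(b$n_bins, c(9L, 10L))
  expect_warning(b0 <- detect_sleep_bouts(make_series(counts, mask = FALSE)),
                 "masked")
  expect_equal(nrow(b0), 0L)
})

test_that("death calling follows the strict >24 h terminal-immobility rule", {
  day <- 1440
  # 25 h terminal zeros after activity -> death at the last active bin
  counts <- c(rep(1, day), rep(0, 25 * 60))
  d <- call_death(make_series(counts))
  expect_true(d$event)
  expect_equal(d$days, 1)  # end of last active bin, 1 day in
  # 23 h terminal zeros -> censored alive
  d <- call_death(make_series(c(rep(1, day), rep(0, 23 * 60))))
  expect_false(d$event)
  # exactly 24 h is not "more than 24 h" -> censored alive
  d <- call_death(make_series(c(rep(1, day), rep(0, 24 * 60))))
  expect_false(d$event)
  # 24 h + 1 min -> death
  d <- call_death(make_series(c(rep(1, day), rep(0, 24 * 60 + 1))))
  expect_true(d$event)
})

test_that("a mid-series 30-h lull with resumed activity is not a death", {
  counts <- c(rep(1, 1440), rep(0, 30 * 60), rep(1, 1440))
  d <- call_death(make_series(counts))
  expect_false(d$event)
  want <- brute_force_death(counts)
  expect_equal(d$event, want$event)
})

test_that("death calling is idempotent and stable under appended zeros", {
  counts <- c(rep(2, 2000), rep(0, 26 * 60))
  d1 <- call_death(make_series(counts))
  d2 <- call_death(make_series(c(counts, rep(0, 1440))))
  expect_true(d1$event && d2$event)
  expect_equal(d1$days, d2$days)
  expect_equal(d1$time, d2$time)
})

test_that("a never-active fly is called dead at the start and flagged", {
  d <- call_death(make_series(rep(0, 2 * 1440)))
  expect_true(d$event)
  expect_equal(d$days, 0)
  expect_equal(d$flag, "never_active")
})

test_that("the after-immobility death convention shifts the time by 24 h", {
  counts <- c(rep(1, 1440), rep(0, 30 * 60))
  d1 <- call_death(make_series(counts))
  d2 <- call_death(make_series(counts), convention = "after_immobility")
  expect_equal(as.numeric(difftime(d2$time, d1$time, units = "hours")), 24)
})

test_that("episode partition of a fully asleep day returns the window lengths", {
  # 2 full recording days, all zeros; day 2 has complete windows
  s <- make_series(rep(0, 2 * 1440))
  b <- detect_sleep_bouts(s)
  p <- partition_episodes(s, b)
  d2 <- p[p$day == 2, ]
  expect_equal(d2$sleep_min[d2$episode == "night"], 360)
  expect_equal(d2$sleep_min[d2$episode == "morning"], 480)
  expect_equal(d2$sleep_min[d2$episode == "siesta"], 240)
  expect_equal(d2$sleep_min[d2$episode == "evening"], 360)
})

test_that("a fully active day has zero episode sleep and random days tile", {
  s <- make_series(rep(1, 1440))
  p <- partition_episodes(s, detect_sleep_bouts(s))
  expect_true(all(p$sleep_min == 0))
  set.seed(11)
  for (rep in 1:10) {
    counts <- rbinom(1440 * 3, 1, 0.4) * rpois(1440 * 3, 2)
    s <- make_series(counts)
    b <- detect_sleep_bouts(s)
    p <- partition_episodes(s, b)
    expect_equal(sum(p$sleep_min), sum(b$duration_min))
    expect_equal(sum(p$activity), sum(counts))
  }
})

test_that("daily summaries mark death and reconcile sleep classes", {
  # fly dying on day 8 of a 20-day recording
  death_min <- 7 * 1440 + 720   # mid-day 8
  counts <- c(rep(1, death_min), rep(0, 20 * 1440 - death_min))
  s <- make_series(counts)
  ds <- summarize_daily(s)
  expect_equal(nrow(ds), 20L)
  expect_equal(sum(ds$alive), 7L)
  expect_true(all(ds$alive[1:7]))
  expect_true(all(!ds$alive[8:20]))
  expect_true(all(is.na(ds$activity[!ds$alive])))
  expect_true(all(!is.na(ds$activity[ds$alive])))

  # immortal all-active fly: 20 summaries with zero sleep
  s <- make_series(rep(1, 20 * 1440))
  ds <- summarize_daily(s)
  expect_equal(nrow(ds), 20L)
  expect_true(all(ds$alive))
  expect_true(all(ds$sleep == 0))

  # short + long sleep equals total sleep, and episodes tile, on a random fly
  set.seed(12)
  counts <- rbinom(20 * 1440, 1, 0.35) * rpois(20 * 1440, 2)
  ds <- summarize_daily(make_series(counts))
  ok <- ds$alive
  expect_equal(ds$sleep_short[ok] + ds$sleep_long[ok], ds$sleep[ok])
  ep_sleep <- ds$sleep_night + ds$sleep_morning + ds$sleep_siesta +
    ds$sleep_evening
  ep_act <- ds$activity_night + ds$activity_morning + ds$activity_siesta +
    ds$activity_evening
  expect_equal(ep_sleep[ok], ds$sleep[ok])
  expect_equal(ep_act[ok], ds$activity[ok])
})
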