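# Exercise-success and exercise-share statistics.

make_exercise_day <- function(window_counts, day = 1, days = 2) {
  # 1-min series with given counts in the ZT7-7.5 window of `day`
  counts <- rep(1, days * 1440)            # active elsewhere, so no death
  w0 <- (day - 1) * 1440 + 7 * 60 + 1
  counts[w0:(w0 + 29)] <- window_counts
  make_series(counts)
}

test_that("no counts in the window means 0% success", {
  s <- make_exercise_day(rep(0, 30))
  expect_equal(as.numeric(exercise_success(s, stimulus_schedule(), 1)), 0)
})

test_that("a count for every stimulus means 100% success", {
  s <- make_exercise_day(rep(3, 30))
  expect_equal(as.numeric(exercise_success(s, stimulus_schedule(), 1)), 100)
})

test_that("capped estimator: constant 1 count/min with 3 stimuli/min gives 30/90", {
  s <- make_exercise_day(rep(1, 30))
  got <- exercise_success(s, stimulus_schedule(), 1)
  expect_equal(as.numeric(got), 100 * 30 / 90)
  expect_equal(attr(got, "mode"), "capped")
})

test_that("counts are capped at the per-bin stimulus count", {
  s <- make_exercise_day(rep(50, 30))  # burst activity cannot exceed 100%
  expect_equal(as.numeric(exercise_success(s, stimulus_schedule(), 1)), 100)
})

test_that("success is invariant to counts outside the exercise window", {
  s1 <- make_exercise_day(rep(1, 30))
  counts2 <- s1$counts
  counts2[1:60] <- 500  # morning burst
  s2 <- make_series(counts2)
  expect_equal(as.numeric(exercise_success(s1, stimulus_schedule(), 1)),
               as.numeric(exercise_success(s2, stimulus_schedule(), 1)))
})

test_that("fine mode scores each stimulus against its response window", {
  # 1 stimulus/min at 1-min bins: fine mode applies
  sched <- stimulus_schedule(duration_min = 10, stimuli_per_minute = 1,
                             active_days = 1)
  win <- c(1, 0, 1, 0, 0, 2, 0, 1, 0, 0)
  counts <- rep(1, 1440)
  counts[(7 * 60 + 1):(7 * 60 + 10)] <- win
  s <- make_series(counts)
  got <- exercise_success(s, sched, 1)
  expect_equal(attr(got, "mode"), "fine")
  expect_equal(as.numeric(got), 100 * sum(win > 0) / 10)
})

test_that("capped and fine estimators agree when responses are binary", {
  # one stimulus per minute, 0/1 counts: both modes count responding stimuli
  set.seed(20)
  sched <- stimulus_schedule(duration_min = 30, stimuli_per_minute = 1,
                             active_days = 1)
  win <- rbinom(30, 1, 0.5)
  counts <- rep(1, 1440)
  counts[(7 * 60 + 1):(7 * 60 + 30)] <- win
  fine <- exercise_success(make_series(counts), sched, 1)
  coarse <- exercise_success(rebin(make_series(counts), 5), sched, 1)
  expect_equal(attr(fine, "mode"), "fine")
  expect_equal(attr(coarse, "mode"), "capped")
  expect_equal(as.numeric(coarse), as.numeric(fine))
})

test_that("group success summary returns Tukey box statistics of fly means", {
  g <- group_success_summary(rep(40, 1))
  expect_equal(g$median, 40)
  expect_equal(g$q25, g$q75)
  g <- group_success_summary(c(10, 20, 30))
  expect_equal(g$median, 20)
  expect_error(group_success_summary(numeric(0)), "valid")
})

test_that("success scales monotonically with the response probability", {
  profs <- default_profiles()
  cfg <- sim_config(list(list(profile = profs$ad, exercising = TRUE, n = 4)),
                    days = 13, seed = 5)
  med_for <- function(p) {
    prof <- genotype_profile("p", p_resp = p)
    means <- vapply(1:4, function(i) {
      sim <- simulate_fly(prof, TRUE, cfg, seed = 1000 + i)
      mean(exercise_success_daily(sim$series, cfg$stimulus)$success,
           na.rm = TRUE)
    }, numeric(1))
    stats::median(means)
  }
  meds <- vapply(c(0.1, 0.5, 0.9), med_for, numeric(1))
  expect_true(all(diff(meds) > 0))
})

test_that("exercise share matches a hand-computed ratio on planted counts", {
  # one exercise day, known window and peak counts
  sched <- stimulus_schedule(active_days = 1)
  counts <- rep(0, 2 * 1440)
  counts[seq(1, 2 * 1440, by = 4)] <- 1  # keep the fly alive throughout
  base <- sum(counts[(7 * 60 + 1):(7 * 60 + 30)])
  counts[(7 * 60 + 1):(7 * 60 + 30)] <- counts[(7 * 60 + 1):(7 * 60 + 30)] + 2
  s <- make_series(counts)
  ds <- summarize_daily(s)
  ex_counts <- base + 2 * 30
  peaks <- ds$activity_morning[1] + ds$activity_evening[1]
  got <- exercise_share(s, sched, ds)
  expect_equal(as.numeric(got), 100 * ex_counts / peaks)
})

test_that("exercise share is 0 without window counts and 100 at parity", {
  sched <- stimulus_schedule(active_days = 1)
  # activity only in morning/evening peaks, none in the window
  counts <- rep(0, 2 * 1440)
  idx_morning <- 1:60             # ZT0-1
  counts[idx_morning] <- 2
  counts[(11 * 60 + 1):(12 * 60)] <- 2  # ZT11-12 evening window
  counts[seq(1, 2 * 1440, by = 300)] <- pmax(1, counts[seq(1, 2 * 1440, by = 300)])
  s <- make_series(counts)
  ds <- summarize_daily(s)
  expect_equal(as.numeric(exercise_share(s, sched, ds)), 0)
})
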