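# The synthetic fly simulator: determinism, degenerate profiles, truth
# recovery, bookkeeping, and planted-parameter monotonicity.

quiet_profile <- function(...) {
  genotype_profile("quiet", baseline_rate = 0,
                   morning_peak = list(height = 0, center_zt = 0.5, width_h = 1),
                   evening_peak = list(height = 0, center_zt = 11.5, width_h = 1),
                   spike_rate = 0, p_resp = 0, ...)
}

test_that("zero template with p_resp 0 gives an all-zero series", {
  cfg <- sim_config(list(list(profile = quiet_profile(), exercising = TRUE,
                              n = 1)), days = 5, seed = 1)
  sim <- simulate_fly(quiet_profile(), TRUE, cfg, seed = 99)
  expect_true(all(sim$series$counts == 0))
})

test_that("the same seed reproduces the identical series", {
  profs <- default_profiles()
  cfg <- sim_config(list(list(profile = profs$ad, exercising = TRUE, n = 1)),
                    days = 8, seed = 1)
  s1 <- simulate_fly(profs$ad, TRUE, cfg, seed = 123)
  s2 <- simulate_fly(profs$ad, TRUE, cfg, seed = 123)
  expect_identical(s1$series$counts, s2$series$counts)
  expect_identical(s1$truth$death_day, s2$truth$death_day)
})

test_that("adding flies or groups never reshuffles existing flies", {
  profs <- default_profiles()
  g1 <- list(profile = profs$ad, exercising = FALSE, n = 2)
  cfg_small <- sim_config(list(g1), days = 3, seed = 9)
  cfg_big <- sim_config(list(modifyList(g1, list(n = 4)),
                             list(profile = profs$wild_type,
                                  exercising = TRUE, n = 2)),
                        days = 3, seed = 9)
  small <- simulate_experiment(cfg_small)
  big <- simulate_experiment(cfg_big)
  for (id in names(small$series)) {
    expect_identical(small$series[[id]]$counts, big$series[[id]]$counts)
  }
})

test_that("pipeline scoring recovers the emitted bout log for bouts >= 5 min", {
  profs <- default_profiles()
  cfg <- sim_config(list(list(profile = profs$wild_type, exercising = FALSE,
                              n = 1)), days = 6, seed = 2)
  sim <- simulate_fly(profs$wild_type, FALSE, cfg, seed = 77)
  got <- detect_sleep_bouts(sim$series)
  truth <- sim$truth$bouts
  truth5 <- truth[truth$duration_min >= 5, ]
  # the fly outlived the recording here, so the logs must agree exactly
  expect_true(is.na(sim$truth$death_day))
  expect_equal(got$start_bin, truth5$start_min)
  expect_equal(got$duration_min, truth5$duration_min)
})

test_that("simulated experiments write one monitor per group and a full truth table", {
  profs <- default_profiles()
  cfg <- sim_config(list(list(profile = profs$ad, exercising = TRUE, n = 32),
                         list(profile = profs$ad, exercising = FALSE, n = 32)),
                    days = 2, seed = 3)
  d <- withr::local_tempdir()
  sim <- simulate_experiment(cfg, out_dir = d)
  expect_equal(length(sim$files), 2L)
  expect_equal(nrow(sim$truth), 64L)
  expect_true(file.exists(sim$truth_file))
  # round trip: files reproduce the in-memory series
  tab <- read_monitor_file(sim$files[1])
  s5 <- to_activity_series(tab, 5)
  expect_equal(s5$counts, sim$series[[sim$truth$fly_id[5]]]$counts)
})

test_that("planted p_resp = 1 forces 100% group median success", {
  prof <- quiet_profile()
  prof$p_resp <- 1
  cfg <- sim_config(list(list(profile = prof, exercising = TRUE, n = 3)),
                    days = 13, seed = 4)
  sim <- simulate_experiment(cfg)
  means <- vapply(sim$series, function(s)
    mean(exercise_success_daily(s, cfg$stimulus)$success, na.rm = TRUE),
    numeric(1))
  expect_equal(group_success_summary(as.numeric(means))$median, 100)
})

test_that("higher fragmentation increases the short-sleep share", {
  share_for <- function(frag) {
    prof <- genotype_profile("f", fragmentation = frag)
    cfg <- sim_config(list(list(profile = prof, exercising = FALSE, n = 4)),
                      days = 6, seed = 5)
    shares <- vapply(1:4, function(i) {
      sim <- simulate_fly(prof, FALSE, cfg, seed = 500 + i)
      ds <- summarize_daily(sim$series)
      sum(ds$sleep_short[ds$alive]) / sum(ds$sleep[ds$alive])
    }, numeric(1))
    mean(shares)
  }
  expect_lt(share_for(1), share_for(2.5))
})

test_that("death truncates the series and the planted time is recoverable", {
  prof <- genotype_profile("m", mortality_median_days = 3,
                           mortality_shape = 0.1)
  cfg <- sim_config(list(list(profile = prof, exercising = FALSE, n = 1)),
                    days = 10, seed = 6)
  sim <- simulate_fly(prof, FALSE, cfg, seed = 11)
  expect_false(is.na(sim$truth$death_day))
  d <- call_death(sim$series)
  expect_true(d$event)
  # called death (last movement) is at or slightly before the planted time
  expect_lte(d$days, sim$truth$death_day)
  expect_gt(d$days, sim$truth$death_day - 1)
})
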