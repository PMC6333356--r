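test_that("well-formed CSV loads with no rejections", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "home_id,timestamp,viewpoint,state,value",
    "H001,2019-01-01 08:00:00,hallway_pir,on,",
    "H001,2019-01-01 08:05:00,bed_pressure,off,",
    "H001,2019-01-01 08:10:00,energy_monitor,on,240"
  ), path)
  s <- load_records(path, "events")
  expect_equal(nrow(s$records), 3)
  expect_equal(nrow(s$report), 0)
  expect_false(s$empty)
  expect_s3_class(s$records$timestamp, "POSIXct")
})

test_that("unknown viewpoint is rejected with its line number", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "home_id,timestamp,viewpoint,state,value",
    "H001,2019-01-01 08:00:00,garage,on,",
    "H001,2019-01-01 08:05:00,hallway_pir,on,"
  ), path)
  s <- load_records(path, "events")
  expect_equal(nrow(s$records), 1)
  expect_equal(s$report$line, 2)
  expect_match(s$report$reason, "garage")
})

test_that("empty file yields empty stream with a warning", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines("home_id,timestamp,viewpoint,state,value", path)
  expect_warning(s <- load_records(path, "events"), "no data rows")
  expect_equal(nrow(s$records), 0)
  expect_true(s$empty)
})

test_that("malformed vitals rows are collected, not dropped silently", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "home_id,timestamp,parameter,value",
    "H001,2019-01-01 09:00:00,body_temperature,36.8",
    "H001,not-a-time,pulse,70",
    "H001,2019-01-01 09:00:00,shoe_size,42"
  ), path)
  s <- load_records(path, "vitals")
  expect_equal(nrow(s$records), 1)
  expect_setequal(s$report$line, c(3, 4))
})

test_that("write then load round-trips simulated streams exactly", {
  coh <- simulate_cohort(quiet_config(2, seed = 5))
  for (ext in c(".csv", ".jsonl")) {
    pe <- withr::local_tempfile(fileext = ext)
    pv <- withr::local_tempfile(fileext = ext)
    write_records(coh$events, pe)
    write_records(coh$vitals, pv)
    ev2 <- load_records(pe, "events")
    vt2 <- load_records(pv, "vitals")
    expect_equal(nrow(ev2$report), 0)
    expect_equal(as.data.frame(ev2$records), as.data.frame(coh$events),
                 tolerance = 1e-9)
    expect_equal(as.data.frame(vt2$records), as.data.frame(coh$vitals),
                 tolerance = 1e-9)
  }
})

test_that("identical config and seed reproduce byte-identical output", {
  cfg <- simulation_config(n_homes = 2, n_days = 7, seed = 1,
                           uti = list(n_episodes = 1, start_days = 3))
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$events, b$events)
  expect_identical(a$vitals, b$vitals)
  expect_identical(a$labels, b$labels)
})

test_that("a config without episodes leaves all ground-truth flags false", {
  coh <- simulate_cohort(quiet_config(7, seed = 2))
  expect_false(any(coh$labels$uti_episode))
  expect_false(any(coh$labels$sleep_disturbed))
  expect_false(any(coh$labels$routine_anomaly))
  expect_false(any(coh$labels$excluded_night))
})

test_that("zero homes, zero days or negative rates are rejected", {
  expect_error(simulation_config(n_homes = 0, n_days = 5, seed = 1))
  expect_error(simulation_config(n_days = 0, seed = 1))
  expect_error(simulation_config(n_days = 5, seed = 1,
                                 bed = list(entry_hour = 22.5, entry_sd_min = 30,
                                            sleep_hours = 8, sleep_sd_min = 45,
                                            bathroom_rate = -1, visit_min = c(4, 8),
                                            turnover_rate = 3)))
  expect_error(simulation_config(n_days = 5))
})

test_that("an injected UTI episode raises night bathroom counts and fever", {
  cfg <- quiet_config(30, seed = 3,
                      uti = list(n_episodes = 1, duration_days = 3,
                                 start_days = 15))
  coh <- simulate_cohort(cfg)
  labs <- coh$labels
  expect_equal(sum(labs$uti_episode), 3)
  ev <- coh$events
  bath <- ev[ev$viewpoint == "bathroom_door_motion", ]
  # count bathroom activations in the 22:00-08:00 night block per night
  night_date <- wd <- as.Date(format(bath$timestamp - 8 * 3600, "%Y-%m-%d"))
  hr <- as.integer(format(bath$timestamp, "%H"))
  at_night <- hr >= 22 | hr < 8
  counts <- table(factor(night_date[at_night], levels = format(labs$date)))
  epi <- labs$uti_episode
  baseline_mean <- cfg$bed$bathroom_rate * mean(2:3)  # visits x events/visit
  expect_true(mean(counts[epi]) > baseline_mean)
  expect_true(mean(counts[epi]) > mean(counts[!epi]))
  temps <- coh$vitals[coh$vitals$parameter == "body_temperature", ]
  epi_temps <- temps$value[as.Date(format(temps$timestamp)) %in% labs$date[epi]]
  expect_true(any(epi_temps > 38))
})

test_that("hourly count means match configured Poisson rates within 3 SE", {
  n_days <- 200
  cfg <- quiet_config(n_days, seed = 11)
  coh <- simulate_cohort(cfg)
  ev <- coh$events
  hr <- as.integer(format(ev$timestamp, "%H"))
  # daytime hours only: nights are shaped by the bed-occupancy process
  for (vp in c("hallway_pir", "kitchen_motion", "pillbox_motion",
               "front_door", "bathroom_door_motion")) {
    for (h in c(10, 14, 16)) {
      rate <- cfg$rate_profiles[[vp]][h + 1]
      n <- sum(ev$viewpoint == vp & hr == h & ev$state == "on")
      se <- sqrt(rate * n_days)
      expect_lt(abs(n - rate * n_days), 3 * se + 1e-9)
    }
  }
})

test_that("only injected episode days are flagged in the labels", {
  cfg <- quiet_config(30, seed = 4,
                      uti = list(n_episodes = 1, duration_days = 2,
                                 start_days = 10),
                      sleep_disturbance = list(n_nights = 2, nights = c(20, 25)))
  labs <- simulate_cohort(cfg)$labels
  expect_equal(which(labs$uti_episode), c(10, 11))
  expect_equal(which(labs$sleep_disturbed), c(20, 25))
  expect_equal(which(labs$routine_anomaly), sort(c(10, 11, 20, 25)))
})
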