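D <- function(s) as.POSIXct(paste("2019-01-10", s), tz = "UTC")
D1 <- function(s) as.POSIXct(paste("2019-01-11", s), tz = "UTC")

test_that("raw epochs are extracted from bed transitions in the night window", {
  ev <- night_events(list(c(D("22:00:00"), D1("06:30:00"))))
  raw <- extract_bed_epochs(ev, "2019-01-10")
  expect_equal(nrow(raw), 1)
  expect_equal(raw$tau_min, 8.5 * 60)
  # events before 18:00 belong to the previous night window
  ev2 <- night_events(list(c(D("13:00:00"), D("13:30:00"))))
  expect_equal(nrow(extract_bed_epochs(ev2, "2019-01-10")), 0)
})

test_that("short occupancy gaps merge into one definitive in-bed epoch", {
  raw <- tibble::tibble(
    onset = c(D("22:00:00"), D("23:01:00")),
    offset = c(D("23:00:00"), D1("06:00:00"))
  )
  clean <- preprocess_bed_epochs(raw, tau_min = 1, delta_merge = 2)
  expect_equal(nrow(clean), 1)
  expect_equal(clean$state, "in")
  expect_equal(clean$dur_min, 8 * 60)
})

test_that("isolated sub-minute occupied blips are removed", {
  raw <- tibble::tibble(
    onset = c(D("20:00:00"), D("22:00:00")),
    offset = c(D("20:00:30"), D1("06:00:00"))
  )
  clean <- preprocess_bed_epochs(raw, tau_min = 1, delta_merge = 2)
  expect_equal(nrow(clean), 1)
  expect_equal(clean$start, D("22:00:00"))
})

test_that("cleaned epochs strictly alternate with positive durations", {
  raw <- tibble::tibble(
    onset = c(D("22:00:00"), D1("00:10:00"), D1("02:00:00")),
    offset = c(D1("00:00:00"), D1("01:30:00"), D1("06:30:00"))
  )
  clean <- preprocess_bed_epochs(raw)
  expect_equal(clean$state, c("in", "out", "in", "out", "in"))
  expect_true(all(clean$dur_min > 0))
  expect_true(all(diff(as.numeric(clean$start)) > 0))
})

test_that("no bed activity at all signals an away night", {
  clean <- preprocess_bed_epochs(tibble::tibble(
    onset = as.POSIXct(character(), tz = "UTC"),
    offset = as.POSIXct(character(), tz = "UTC")
  ))
  expect_true(attr(clean, "away"))
  night <- label_sleep_states(clean)
  expect_false(night$valid)
  expect_equal(night$reason, "away")
})

test_that("sleep onset requires an in-bed epoch beyond the derived threshold", {
  thr <- stage_thresholds()
  expect_equal(thr$onset_min, 21.5)
  expect_equal(thr$restless_max, 11)
  # first epoch 30 min > 21.5: onset at its start
  ev <- night_events(list(
    c(D("22:00:00"), D("22:30:00")),
    c(D("22:40:00"), D1("06:00:00"))
  ))
  night <- label_sleep_states(preprocess_bed_epochs(extract_bed_epochs(ev, "2019-01-10")),
                              ambient = ev)
  expect_true(night$valid)
  expect_equal(night$onset, D("22:00:00"))
  # a 15-min first epoch is not onset; onset moves to the long epoch
  ev2 <- night_events(list(
    c(D("22:00:00"), D("22:15:00")),
    c(D("22:40:00"), D1("06:00:00"))
  ))
  night2 <- label_sleep_states(preprocess_bed_epochs(extract_bed_epochs(ev2, "2019-01-10")),
                               ambient = ev2)
  expect_equal(night2$onset, D("22:40:00"))
})

test_that("in-bed epochs are staged by duration", {
  ev <- night_events(list(
    c(D("22:00:00"), D1("00:00:00")),   # 120 min -> good (>= one full cycle)
    c(D1("00:10:00"), D1("00:18:00")),  # 8 min -> restless (< 11)
    c(D1("00:30:00"), D1("01:30:00")),  # 60 min -> moderate
    c(D1("01:40:00"), D1("06:00:00"))   # 260 min -> good
  ))
  night <- label_sleep_states(preprocess_bed_epochs(extract_bed_epochs(ev, "2019-01-10")),
                              ambient = ev)
  states <- night$blocks$state[night$blocks$state != "out_of_bed" &
                                 night$blocks$state != "wandering"]
  expect_equal(states, c("sleep_good", "restless", "sleep_moderate", "sleep_good"))
  expect_equal(night$restless_min, 8)
})

test_that("out-of-bed epochs become wandering only with spread ambient activity", {
  amb <- events_tbl(
    paste("2019-01-11", c("02:05:00", "02:10:00", "02:20:00", "02:25:00",
                          "02:30:00")),
    c("hallway_pir", "hallway_pir", "kitchen_motion", "hallway_pir",
      "kitchen_motion")
  )
  ev <- night_events(list(
    c(D("22:00:00"), D1("02:00:00")),
    c(D1("02:40:00"), D1("06:00:00"))   # 40-min gap with activity
  ), ambient = amb)
  night <- label_sleep_states(preprocess_bed_epochs(extract_bed_epochs(ev, "2019-01-10")),
                              ambient = ev)
  expect_equal(night$blocks$state[2], "wandering")
  expect_equal(night$wandering_min, 40)
  # same trace with a single activation: plain out-of-bed
  ev2 <- night_events(list(
    c(D("22:00:00"), D1("02:00:00")),
    c(D1("02:40:00"), D1("06:00:00"))
  ), ambient = amb[1, ])
  night2 <- label_sleep_states(preprocess_bed_epochs(extract_bed_epochs(ev2, "2019-01-10")),
                               ambient = ev2)
  expect_equal(night2$blocks$state[2], "out_of_bed")
})

test_that("bedroom-channel activity does not count towards wandering", {
  amb <- events_tbl(
    paste("2019-01-11", c("02:05:00", "02:10:00", "02:20:00", "02:25:00")),
    c("bedroom_door_motion", "bedroom_door_motion", "bed_pressure",
      "bedroom_door_motion")
  )
  ev <- night_events(list(
    c(D("22:00:00"), D1("02:00:00")),
    c(D1("02:40:00"), D1("06:00:00"))
  ), ambient = amb)
  night <- label_sleep_states(preprocess_bed_epochs(extract_bed_epochs(ev, "2019-01-10")),
                              ambient = ev)
  expect_equal(night$blocks$state[2], "out_of_bed")
})

test_that("nights under three hours in bed are excluded as short sleep", {
  ev <- night_events(list(c(D("23:00:00"), D1("01:30:00"))))  # 2.5 h
  night <- label_sleep_states(preprocess_bed_epochs(extract_bed_epochs(ev, "2019-01-10")),
                              ambient = ev)
  expect_false(night$valid)
  expect_equal(night$reason, "short_sleep")
})

test_that("a long all-sensor silence marks the night technical", {
  # bed epochs only at the window edges leave > 6 h of dead air
  ev <- night_events(list(
    c(D("18:30:00"), D("19:00:00")),
    c(D1("04:00:00"), D1("08:00:00"))
  ))
  night <- label_sleep_states(preprocess_bed_epochs(extract_bed_epochs(ev, "2019-01-10")),
                              ambient = ev)
  expect_false(night$valid)
  expect_equal(night$reason, "technical")
})

test_that("block durations reconcile with onset and offset", {
  coh <- simulate_cohort(quiet_config(5, seed = 41))
  nights <- analyse_sleep(coh, as.Date("2019-01-01") + 0:3)
  for (n in nights[vapply(nights, `[[`, TRUE, "valid")]) {
    expect_equal(sum(n$blocks$dur_min),
                 as.numeric(difftime(n$offset, n$onset, units = "mins")),
                 tolerance = 1e-6)
    expect_false(is.unsorted(as.numeric(n$blocks$start)))
  }
})

test_that("labelling is deterministic and idempotent on a fixed trace", {
  coh <- simulate_cohort(quiet_config(3, seed = 42))
  a <- analyse_sleep(coh, as.Date("2019-01-01"))
  b <- analyse_sleep(coh, as.Date("2019-01-01"))
  expect_identical(summarise_nights(a), summarise_nights(b))
})

test_that("personal boundaries follow the history mean and spread", {
  mk <- function(sleep, rw) {
    tibble::tibble(date = as.Date("2019-01-01") + seq_along(sleep) - 1,
                   valid = TRUE, reason = "valid", sleep_min = sleep,
                   restless_min = rw, wandering_min = 0, out_of_bed_min = 0)
  }
  hist30 <- mk(rep(420, 30), rep(10, 30))
  b <- adaptive_boundaries(hist30, xi = 2)
  expect_equal(b$min_sleep_min, 420)
  expect_equal(b$max_rw_min, 10)
  hist_var <- mk(rnorm(30, 420, 20), abs(rnorm(30, 15, 5)))
  b1 <- adaptive_boundaries(hist_var, xi = 1)
  b2 <- adaptive_boundaries(hist_var, xi = 2)
  expect_lt(b2$min_sleep_min, b1$min_sleep_min)
  expect_gt(b2$max_rw_min, b1$max_rw_min)
  expect_error(adaptive_boundaries(mk(rep(400, 29), rep(5, 29))), "at least 30")
})

test_that("disturbance detection applies the boundary rules", {
  bounds <- structure(list(min_sleep_min = 350, max_rw_min = 60),
                      class = "dws_sleep_bounds")
  mk_night <- function(valid, sleep, rw, reason = "valid") {
    structure(list(valid = valid, reason = reason, sleep_min = sleep,
                   restless_min = rw, wandering_min = 0), class = "dws_night")
  }
  expect_equal(detect_disturbance(mk_night(TRUE, 200, 10), bounds), "disturbed")
  expect_equal(detect_disturbance(mk_night(TRUE, 420, 90), bounds), "disturbed")
  expect_equal(detect_disturbance(mk_night(TRUE, 420, 20), bounds), "normal")
  expect_equal(detect_disturbance(mk_night(FALSE, 0, 0, "away"), bounds),
               "excluded")
})
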