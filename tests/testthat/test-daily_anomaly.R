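test_that("daily matrices are min-max scaled into [0,1]", {
  coh <- simulate_cohort(quiet_config(10, seed = 31))
  dm <- build_daily_matrices(coh, "2019-01-01", "2019-01-10")
  expect_equal(length(dm$days), 10)
  for (m in dm$days) {
    expect_equal(dim(m), c(24, 10))
    expect_true(all(m >= 0 & m <= 1))
  }
  # a sensor that scales by training extremes reaches both bounds somewhere
  stacked <- do.call(rbind, dm$days)
  expect_true(any(stacked == 1))
})

test_that("test-day values are clipped by training-period extremes", {
  ev <- dplyr::bind_rows(
    events_tbl(sprintf("2019-01-%02d 10:%02d:00", rep(1:3, each = 2), 1:6 * 5),
               "hallway_pir"),
    events_tbl(sprintf("2019-01-04 10:%02d:00", 1:50), "hallway_pir")
  )
  dm <- build_daily_matrices(ev, "2019-01-04", "2019-01-04",
                             train_start = "2019-01-01",
                             train_end = "2019-01-03")
  expect_equal(unname(dm$days[[1]][11, "hallway_pir"]), 1)  # clipped, not > 1
})

test_that("a constant sensor scales to an all-zero column", {
  # energy monitor reporting the same wattage every hour: zero range
  times <- as.POSIXct("2019-01-01 00:30:00", tz = "UTC") + (0:119) * 3600
  ev <- tibble::tibble(home_id = "H001", timestamp = times,
                       viewpoint = "energy_monitor", state = "on", value = 200)
  dm <- build_daily_matrices(ev, "2019-01-01", "2019-01-05")
  for (m in dm$days) expect_equal(unname(m[, "energy_monitor"]), rep(0, 24))
})

test_that("an event-free day is a zero matrix with 24 missingness flags", {
  ev <- events_tbl("2019-01-01 09:00:00", "hallway_pir")
  dm <- build_daily_matrices(ev, "2019-01-01", "2019-01-02")
  expect_equal(sum(dm$days[[2]]), 0)
  expect_equal(sum(dm$missing[[2]]), 24)
  expect_equal(sum(dm$missing[[1]]), 23)
})

test_that("a day identical to a training day is labelled normal", {
  set.seed(32)
  base <- matrix(runif(240, 0.2, 0.8), 24, 10)
  train <- lapply(1:35, function(i) pmin(pmax(base + rnorm(240, 0, 0.05), 0), 1))
  res <- fit_and_label(train, train[3], seed = 1)
  expect_equal(res$labels$label, "normal")
})

test_that("a saturated night stands out as abnormal", {
  set.seed(33)
  quiet_night <- matrix(0.1, 24, 10)
  quiet_night[8:22, ] <- 0.5
  train <- lapply(1:35, function(i) {
    pmin(pmax(quiet_night + rnorm(240, 0, 0.05), 0), 1)
  })
  anomaly <- quiet_night
  anomaly[1:6, ] <- 1
  res <- fit_and_label(train, c(train[1], list(anomaly)), seed = 1)
  expect_gt(res$labels$score[2], res$labels$score[1])
  expect_equal(res$labels$label[2], "abnormal")
})

test_that("scores are deterministic given the seed", {
  set.seed(34)
  train <- lapply(1:32, function(i) matrix(runif(240), 24, 10))
  test <- lapply(1:5, function(i) matrix(runif(240), 24, 10))
  a <- fit_and_label(train, test, seed = 7)
  b <- fit_and_label(train, test, seed = 7)
  expect_identical(a$labels, b$labels)
})

test_that("short training requires the explicit override", {
  set.seed(35)
  train <- lapply(1:10, function(i) matrix(runif(240), 24, 10))
  expect_error(fit_and_label(train, train[1], seed = 1), "30 training days")
  res <- fit_and_label(train, train[1], seed = 1, allow_short = TRUE)
  expect_equal(nrow(res$labels), 1)
})

test_that("scores do not depend on event row order", {
  coh <- simulate_cohort(quiet_config(35, seed = 36))
  ev <- coh$events
  set.seed(1)
  shuffled <- ev[sample(nrow(ev)), ]
  d1 <- build_daily_matrices(ev, "2019-01-01", "2019-02-04")
  d2 <- build_daily_matrices(shuffled, "2019-01-01", "2019-02-04")
  s1 <- fit_and_label(d1, d1, seed = 3)
  s2 <- fit_and_label(d2, d2, seed = 3)
  expect_equal(s1$labels, s2$labels)
})

test_that("injected anomalous days rank near the top of the scores", {
  # an infection episode disrupts the whole day (daytime bathroom frequency,
  # night-time visits and wandering), the kind of anomaly the day detector
  # is meant to surface
  cfg <- quiet_config(70, seed = 37,
                      uti = list(n_episodes = 1, start_days = 50))
  coh <- simulate_cohort(cfg)
  train <- build_daily_matrices(coh, "2019-01-01", "2019-01-30")
  test <- build_daily_matrices(coh, "2019-01-31", "2019-03-11",
                               train_start = "2019-01-01",
                               train_end = "2019-01-30")
  res <- fit_and_label(train, test, seed = 2)
  ev <- evaluate_day_scores(res$labels, coh$labels)
  expect_equal(ev$n_anomalous, 3)
  expect_true(all(ev$anomalous_ranks <= ceiling(0.1 * ev$n_scored)))
})
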