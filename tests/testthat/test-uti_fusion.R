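test_that("only readings strictly above threshold raise temperature alerts", {
  v <- vitals_tbl(c("2019-01-01 09:00:00", "2019-01-01 21:00:00",
                    "2019-01-02 09:00:00"),
                  "body_temperature", c(36.8, 38.5, 38.0))
  a <- temperature_alerts(v)
  expect_equal(nrow(a), 1)
  expect_equal(a$value, 38.5)
  expect_equal(nrow(temperature_alerts(v[0, ])), 0)
  # non-temperature parameters are ignored even when numerically large
  v2 <- vitals_tbl("2019-01-01 09:00:00", "pulse", 120)
  expect_equal(nrow(temperature_alerts(v2)), 0)
})

test_that("rare-pattern windows raise alerts stamped at the window end", {
  profile <- toy_profile("night")
  windows <- list(windows = tibble::tibble(
    window_start = as.POSIXct(c("2019-01-03 00:00:00", "2019-01-04 00:00:00"),
                              tz = "UTC"),
    category = "night",
    counts = list(toy_window(c("hallway_pir", "kitchen_motion",
                               "living_room_pir")),
                  toy_window("bed_pressure"))
  ))
  a <- rsfp_alerts(windows, profile, home_id = "H009")
  expect_equal(nrow(a), 1)
  expect_equal(a$timestamp, as.POSIXct("2019-01-03 06:00:00", tz = "UTC"))
  expect_equal(a$home_id, "H009")
  empty <- rsfp_alerts(list(windows = tibble::tibble(
    window_start = as.POSIXct(character(), tz = "UTC"),
    category = character(), counts = list()
  )), profile)
  expect_equal(nrow(empty), 0)
})

test_that("fusion pairs evidence within the window and deduplicates", {
  t0 <- as.POSIXct("2019-01-05 09:00:00", tz = "UTC")
  temp <- tibble::tibble(home_id = "H001", timestamp = t0, value = 38.6)
  mk_rsfp <- function(ts) {
    tibble::tibble(home_id = "H001", timestamp = ts, window_start = ts - 6 * 3600,
                   cluster = 2L)
  }
  expect_equal(nrow(fuse_decisions(temp, mk_rsfp(t0 + 20 * 3600))), 1)
  expect_equal(nrow(fuse_decisions(temp, mk_rsfp(t0 + 30 * 3600))), 0)
  # two rare-pattern alerts near one fever: a single deduplicated alert
  two <- dplyr::bind_rows(mk_rsfp(t0 + 2 * 3600), mk_rsfp(t0 + 5 * 3600))
  fused <- fuse_decisions(temp, two)
  expect_equal(nrow(fused), 1)
  # every alert carries both evidence types
  expect_false(any(is.na(fused$temp_time)))
  expect_false(any(is.na(fused$rsfp_time)))
  expect_lte(abs(as.numeric(difftime(fused$temp_time, fused$rsfp_time,
                                     units = "hours"))), 24)
})

test_that("fusion is symmetric in evidence order and list ordering", {
  t0 <- as.POSIXct("2019-01-05 09:00:00", tz = "UTC")
  temp <- tibble::tibble(home_id = "H001",
                         timestamp = c(t0 + 50 * 3600, t0), value = c(38.2, 38.6))
  rsfp <- tibble::tibble(home_id = "H001",
                         timestamp = c(t0 + 10 * 3600, t0 + 60 * 3600),
                         window_start = t0, cluster = 1L)
  a <- fuse_decisions(temp, rsfp)
  b <- fuse_decisions(temp[2:1, ], rsfp[2:1, ])
  expect_equal(a, b)
  expect_equal(nrow(a), 2)  # two well-separated fused alerts
})

test_that("homes are fused independently", {
  t0 <- as.POSIXct("2019-01-05 09:00:00", tz = "UTC")
  temp <- tibble::tibble(home_id = "H001", timestamp = t0, value = 38.6)
  rsfp <- tibble::tibble(home_id = "H002", timestamp = t0 + 3600,
                         window_start = t0, cluster = 1L)
  expect_equal(nrow(fuse_decisions(temp, rsfp)), 0)
})

test_that("the one-class baseline separates febrile-frequent from routine", {
  set.seed(30)
  train <- data.frame(bathroom_freq = rnorm(20, 12, 1.5),
                      temperature = rnorm(20, 38.5, 0.2))
  test <- data.frame(
    bathroom_freq = c(mean(train$bathroom_freq), 2),
    temperature = c(mean(train$temperature), 36.5)
  )
  res <- one_class_baseline(train, test)
  expect_true(res$flag[1])    # the training centroid is UTI-like
  expect_false(res$flag[2])   # a routine day is not
  expect_false(res$degenerate)
})

test_that("degenerate one-class training falls back to a distance rule", {
  train <- data.frame(bathroom_freq = rep(10, 6), temperature = rep(38.4, 6))
  test <- data.frame(bathroom_freq = c(10, 3), temperature = c(38.4, 36.6))
  res <- one_class_baseline(train, test)
  expect_true(res$degenerate)
  expect_equal(res$flag, c(TRUE, FALSE))
  expect_error(one_class_baseline(train[1:3, ], test), "at least 5")
})

test_that("daily bathroom frequency counts activations per home-day", {
  ev <- dplyr::bind_rows(
    events_tbl(c("2019-01-01 08:00:00", "2019-01-01 12:00:00"),
               "bathroom_door_motion"),
    events_tbl("2019-01-02 09:00:00", "bathroom_door_motion"),
    events_tbl("2019-01-01 10:00:00", "hallway_pir")
  )
  bf <- bathroom_frequency(ev)
  expect_equal(bf$bathroom_freq, c(2, 1))
})
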