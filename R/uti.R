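#' Raised body-temperature alerts
#'
#' Emits one alert per body-temperature reading strictly greater than the
#' threshold (default 38 degrees Celsius, the febrile cut-off used for
#' infection screening). Other vital parameters are ignored.
#'
#' @param vitals Vitals tibble (or `dws_stream` / `dws_cohort`).
#' @param threshold Temperature cut-off in degrees C, strict inequality.
#' @return Tibble of alerts: `home_id`, `timestamp`, `value`.
#' @export
temperature_alerts <- function(vitals, threshold = 38) {
  if (inherits(vitals, "dws_stream")) vitals <- vitals$records
  if (inherits(vitals, "dws_cohort")) vitals <- vitals$vitals
  hit <- vitals$parameter == "body_temperature" & vitals$value > threshold
  out <- vitals[hit, c("home_id", "timestamp", "value"), drop = FALSE]
  tibble::as_tibble(out)
}

#' Rare-pattern (RSFP) alerts
#'
#' Classifies each six-hour window against the activity profile of its time
#' category and emits an alert for every window that lands in a rarely
#' repetitive (RSFP) cluster. The alert timestamp is the window end.
#'
#' @param windows A `dws_sfp_set` (from [build_sfp_windows()]).
#' @param profile A [build_activity_profile()] result covering the windows'
#'   categories.
#' @param home_id Home identifier attached to the alerts.
#' @return Tibble of alerts: `home_id`, `timestamp` (window end),
#'   `window_start`, `cluster`.
#' @export
rsfp_alerts <- function(windows, profile, home_id = "H001") {
  w <- windows$windows
  rows <- lapply(seq_len(nrow(w)), function(i) {
    cls <- classify_window(w$counts[[i]], profile, w$category[i])
    if (cls$category == "RSFP") {
      tibble::tibble(
        home_id = home_id,
        timestamp = w$window_start[i] + 6 * 3600,
        window_start = w$window_start[i],
        cluster = cls$cluster
      )
    } else {
      NULL
    }
  })
  out <- dplyr::bind_rows(rows)
  if (!nrow(out)) {
    out <- tibble::tibble(
      home_id = character(), timestamp = as.POSIXct(character(), tz = "UTC"),
      window_start = as.POSIXct(character(), tz = "UTC"), cluster = integer()
    )
  }
  out
}

#' Fuse temperature and rare-pattern alerts into UTI alerts
#'
#' Emits a UTI alert whenever a raised-temperature alert and an RSFP alert
#' from the same home occur within `window_hours` of each other. Alerts are
#' deduplicated to at most one per home per rolling `window_hours`, so a
#' cluster of coincident evidence produces a single notification. The fusion
#' is symmetric in which evidence arrives first.
#'
#' @param temp_alerts Output of [temperature_alerts()].
#' @param rsfp_alerts Output of [rsfp_alerts()].
#' @param window_hours Fusion window, default 24.
#' @return Tibble of UTI alerts: `home_id`, `timestamp` (the later of the
#'   two evidence timestamps), `temp_time`, `temp_value`, `rsfp_time`,
#'   `rsfp_cluster`.
#' @export
fuse_decisions <- function(temp_alerts, rsfp_alerts, window_hours = 24) {
  empty <- tibble::tibble(
    home_id = character(), timestamp = as.POSIXct(character(), tz = "UTC"),
    temp_time = as.POSIXct(character(), tz = "UTC"), temp_value = numeric(),
    rsfp_time = as.POSIXct(character(), tz = "UTC"), rsfp_cluster = integer()
  )
  if (!nrow(temp_alerts) || !nrow(rsfp_alerts)) {
    return(empty)
  }
  out <- list()
  for (h in sort(unique(intersect(temp_alerts$home_id, rsfp_alerts$home_id)))) {
    ta <- temp_alerts[temp_alerts$home_id == h, , drop = FALSE]
    ra <- rsfp_alerts[rsfp_alerts$home_id == h, , drop = FALSE]
    ta <- ta[order(ta$timestamp), , drop = FALSE]
    ra <- ra[order(ra$timestamp), , drop = FALSE]
    # all evidence pairs within the window, in time order of the pair
    pairs <- expand.grid(i = seq_len(nrow(ta)), j = seq_len(nrow(ra)))
    dt <- abs(as.numeric(difftime(ta$timestamp[pairs$i], ra$timestamp[pairs$j],
                                  units = "hours")))
    pairs <- pairs[dt <= window_hours, , drop = FALSE]
    if (!nrow(pairs)) next
    pair_time <- pmax(ta$timestamp[pairs$i], ra$timestamp[pairs$j])
    ord <- order(pair_time)
    pairs <- pairs[ord, , drop = FALSE]
    pair_time <- pair_time[ord]
    last_emit <- as.POSIXct(-Inf, origin = "1970-01-01", tz = "UTC")
    for (p in seq_len(nrow(pairs))) {
      if (as.numeric(difftime(pair_time[p], last_emit, units = "hours")) <
          window_hours) {
        next  # deduplicate: one alert per home per rolling window
      }
      out[[length(out) + 1L]] <- tibble::tibble(
        home_id = h,
        timestamp = pair_time[p],
        temp_time = ta$timestamp[pairs$i[p]],
        temp_value = ta$value[pairs$i[p]],
        rsfp_time = ra$timestamp[pairs$j[p]],
        rsfp_cluster = ra$cluster[pairs$j[p]]
      )
      last_emit <- pair_time[p]
    }
  }
  if (!length(out)) {
    return(empty)
  }
  dplyr::bind_rows(out)
}

#' One-class SVM baseline for UTI detection
#'
#' The supervised comparison model: a one-class support vector machine with
#' radial-basis kernel trained on clinician-annotated UTI-positive feature
#' pairs (daily bathroom-visit frequency, body temperature). Features are
#' standardised with the training statistics; test points falling inside the
#' learned boundary are flagged UTI-like. Defaults follow the study's grid
#' search: kernel width `sigma = 1e-2` (the RBF `gamma`), `nu = 0.05`.
#'
#' Degenerate training sets (all points identical) fall back to a Euclidean
#' distance threshold around the common point, with a `degenerate` flag.
#'
#' @param train Data frame / matrix with columns `bathroom_freq`, `temperature`
#'   of UTI-positive observations (>= 5 rows).
#' @param test Data frame / matrix with the same columns.
#' @param sigma RBF kernel width (gamma), default `1e-2`.
#' @param nu One-class nu parameter, default 0.05.
#' @return List: `flag` (logical per test row, TRUE = UTI-like), `degenerate`,
#'   `model`.
#' @export
one_class_baseline <- function(train, test, sigma = 1e-2, nu = 0.05) {
  stopifnot(sigma > 0, nu > 0, nu < 1)
  train <- as.matrix(as.data.frame(train)[, c("bathroom_freq", "temperature")])
  test <- as.matrix(as.data.frame(test)[, c("bathroom_freq", "temperature")])
  if (nrow(train) < 5) stop("need at least 5 training points")
  mu <- colMeans(train)
  sdv <- apply(train, 2, sd)
  if (all(sdv < 1e-12)) {
    d <- sqrt(colSums((t(test) - mu)^2))
    return(list(flag = d < 0.5, degenerate = TRUE, model = NULL))
  }
  sdv[sdv < 1e-12] <- 1
  tr <- sweep(sweep(train, 2, mu), 2, sdv, "/")
  te <- sweep(sweep(test, 2, mu), 2, sdv, "/")
  fit <- e1071::svm(tr, y = NULL, type = "one-classification",
                    kernel = "radial", gamma = sigma, nu = nu, scale = FALSE)
  list(flag = as.logical(predict(fit, te)), degenerate = FALSE, model = fit)
}

#' Daily bathroom-visit frequency
#'
#' Counts bathroom-door activations per home-day, the frequency feature of
#' the one-class baseline.
#'
#' @param events Event tibble (or `dws_stream` / `dws_cohort`).
#' @return Tibble: `home_id`, `date`, `bathroom_freq`.
#' @export
bathroom_frequency <- function(events) {
  if (inherits(events, "dws_stream")) events <- events$records
  if (inherits(events, "dws_cohort")) events <- events$events
  ev <- events[events$viewpoint == "bathroom_door_motion" &
                 (is.na(events$state) | events$state == "on"), , drop = FALSE]
  ev$date <- wallclock_date(ev$timestamp)
  dplyr::count(ev, .data$home_id, .data$date, name = "bathroom_freq")
}
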