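#' Default hourly activation-rate profiles
#'
#' Mean Poisson event rates (events per hour) for each sensor viewpoint as a
#' function of hour of day (0-23), emulating a single older adult living
#' alone: meal-time kitchen peaks, daytime presence in the living room and
#' hallway, twice-daily pillbox access, and near-silence overnight. Bed
#' pressure is not listed here because nightly occupancy is generated as
#' explicit epochs, and the energy monitor is generated as one wattage
#' reading per hour.
#'
#' @return Named list of 24-element numeric vectors.
#' @export
default_rate_profiles <- function() {
  h <- 0:23
  day <- function(lo, hi, level, night = 0.05) {
    ifelse(h >= lo & h < hi, level, night)
  }
  list(
    hallway_pir = day(8, 22, 4, night = 0.35),
    living_room_pir = day(9, 22, 5, night = 0.2) +
      ifelse(h >= 19 & h < 22, 2, 0),
    kitchen_motion = day(9, 21, 1, night = 0.12) +
      ifelse(h %in% c(8, 12, 13, 18), 3, 0),
    pillbox_motion = ifelse(h %in% c(9, 21), 0.6, 0.02),
    bedroom_door_motion = ifelse(h %in% c(7, 8, 22, 23), 2, day(9, 21, 0.3, 0.1)),
    bathroom_door_motion = day(7, 22, 0.8, night = 0.1),
    chair_pressure = day(9, 22, 1.5, night = 0.02),
    front_door = day(9, 18, 0.2, night = 0.01)
  )
}

#' Build a cohort simulation configuration
#'
#' Assembles and validates the parameter set of the synthetic smart-home
#' simulator. Defaults describe a realistic single-occupant household of an
#' older adult: bed entry around 22:30, roughly eight hours in bed, a
#' baseline nocturia rate of 0.8 bathroom visits per night, twice-daily
#' vitals sessions, occasional guests and rare benign restless nights.
#'
#' @param n_homes Number of simulated households.
#' @param n_days Number of simulated days per household.
#' @param seed Mandatory RNG seed; the same config + seed reproduces
#'   byte-identical output.
#' @param start_date First simulated calendar date.
#' @param rate_profiles Named list of 24-hour Poisson rate vectors, see
#'   [default_rate_profiles()].
#' @param bed Bed-occupancy schedule: `entry_hour` (mean clock hour of bed
#'   entry), `entry_sd_min`, `sleep_hours` (mean), `sleep_sd_min`,
#'   `bathroom_rate` (mean nightly bathroom visits), `visit_min` (range of
#'   visit durations, minutes), `turnover_rate` (mean nightly turn-over
#'   blips, each a sub-minute bed-pressure gap).
#' @param vitals Named list of `c(mean, sd)` per vital parameter plus
#'   `sessions` (clock hours of the measurement sessions).
#' @param uti UTI episode spec: `n_episodes`, `duration_days`,
#'   `bathroom_multiplier` (nightly visit-rate multiplier),
#'   `day_bathroom_multiplier` (daytime bathroom-rate multiplier — urinary
#'   frequency is a day-long symptom), `temp_mean` and `temp_sd` (feverish
#'   body temperature on episode days), `wander_bouts`, `wander_min` (range
#'   of bout lengths, minutes). `NULL` disables.
#' @param sleep_disturbance Disturbed-night spec: `n_nights`, `bouts`,
#'   `bout_min` (range of wandering bout lengths, minutes). `NULL` disables.
#' @param nuisance Nuisance spec: `guest_prob` (per-day probability of a
#'   guest visit), `guest_hours`, `guest_multiplier`, `pet_rate` (extra
#'   flat hourly motion rate), `missing_prob` (per-day probability of a
#'   whole-home technical outage), `restless_prob` (per-night probability of
#'   a benign irregular night: a wandering spell, a sleepless spell in the
#'   living room, or a heavy-nocturia night), `upset_day_prob` (per-day
#'   probability of a benign bathroom-heavy upset day).
#' @return A validated list of class `dws_sim_config`.
#' @export
simulation_config <- function(
    n_homes = 1,
    n_days = 30,
    seed,
    start_date = as.Date("2019-01-01"),
    rate_profiles = default_rate_profiles(),
    bed = list(
      entry_hour = 22.5, entry_sd_min = 30, sleep_hours = 8, sleep_sd_min = 45,
      bathroom_rate = 0.8, visit_min = c(4, 8), turnover_rate = 3
    ),
    vitals = list(
      sessions = c(9, 21),
      systolic_bp = c(125, 8), diastolic_bp = c(75, 6), pulse = c(72, 6),
      body_temperature = c(36.7, 0.25), spo2 = c(97, 1),
      weight = c(70, 0.4), hydration = c(50, 6)
    ),
    uti = NULL,
    sleep_disturbance = NULL,
    nuisance = list(
      guest_prob = 0.05, guest_hours = 3, guest_multiplier = 3,
      pet_rate = 0.05, missing_prob = 0.01, restless_prob = 0.12,
      upset_day_prob = 0.04
    )) {
  if (missing(seed) || is.null(seed)) stop("a seed is mandatory")
  if (n_homes < 1 || n_days < 1) stop("n_homes and n_days must be >= 1")
  stopifnot(all(vapply(rate_profiles, length, 1L) == 24))
  if (any(unlist(rate_profiles) < 0)) stop("rate profiles must be non-negative")
  if (bed$bathroom_rate < 0 || bed$turnover_rate < 0 ||
      bed$sleep_hours <= 0 || any(bed$visit_min <= 0)) {
    stop("bed schedule parameters must be non-negative")
  }
  for (p in vital_parameters()) {
    if (is.null(vitals[[p]])) stop("vitals spec missing parameter ", p)
    if (vitals[[p]][2] < 0) stop("vitals SD must be non-negative")
  }
  if (!is.null(uti)) {
    uti <- utils::modifyList(
      list(n_episodes = 1, duration_days = 3, bathroom_multiplier = 6,
           day_bathroom_multiplier = 4, temp_mean = 38.5, temp_sd = 0.3,
           wander_bouts = 2, wander_min = c(25, 45), start_days = NULL),
      uti
    )
    if (uti$bathroom_multiplier < 0 || uti$duration_days < 1) {
      stop("invalid uti episode spec")
    }
  }
  if (!is.null(sleep_disturbance)) {
    sleep_disturbance <- utils::modifyList(
      list(n_nights = 1, bouts = 3, bout_min = c(30, 60), nights = NULL),
      sleep_disturbance
    )
  }
  nuisance <- utils::modifyList(
    list(guest_prob = 0.05, guest_hours = 3, guest_multiplier = 3,
         pet_rate = 0.05, missing_prob = 0.01, restless_prob = 0.12,
         upset_day_prob = 0.04),
    nuisance
  )
  structure(
    list(
      n_homes = as.integer(n_homes), n_days = as.integer(n_days),
      seed = as.integer(seed), start_date = as.Date(start_date),
      rate_profiles = rate_profiles, bed = bed, vitals = vitals,
      uti = uti, sleep_disturbance = sleep_disturbance, nuisance = nuisance
    ),
    class = "dws_sim_config"
  )
}

#' Simulate a smart-home cohort
#'
#' Generates timestamped sensor events, twice-daily vitals and per-day ground
#' truth labels for `n_homes` households over `n_days`, emulating per-hour
#' activity with time-of-day structure, nightly bed-occupancy epochs with
#' bathroom visits and turn-over blips, guest/pet nuisance activity,
#' whole-home technical outages, and injectable UTI episodes (raised
#' night-time bathroom frequency, fever, night wandering) and
#' sleep-disturbance nights.
#'
#' @param config A [simulation_config()].
#' @return List of class `dws_cohort`: `events` (tibble
#'   `home_id,timestamp,viewpoint,state,value`), `vitals` (tibble
#'   `home_id,timestamp,parameter,value`), `labels` (tibble
#'   `home_id,date,uti_episode,sleep_disturbed,routine_anomaly,
#'   excluded_night`), and `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "dws_sim_config"))
  with_local_seed(config$seed, {
    homes <- sprintf("H%03d", seq_len(config$n_homes))
    parts <- lapply(homes, function(h) simulate_home(h, config))
    events <- dplyr::bind_rows(lapply(parts, `[[`, "events"))
    vitals <- dplyr::bind_rows(lapply(parts, `[[`, "vitals"))
    labels <- dplyr::bind_rows(lapply(parts, `[[`, "labels"))
    events <- dplyr::arrange(events, .data$home_id, .data$timestamp)
    vitals <- dplyr::arrange(vitals, .data$home_id, .data$timestamp)
    structure(
      list(events = events, vitals = vitals, labels = labels, config = config),
      class = "dws_cohort"
    )
  })
}

#' @export
print.dws_cohort <- function(x, ...) {
  cat("<dws_cohort> ", x$config$n_homes, " home(s) x ", x$config$n_days,
      " day(s): ", nrow(x$events), " events, ", nrow(x$vitals),
      " vitals readings\n", sep = "")
  invisible(x)
}

# ---- internals ------------------------------------------------------------

simulate_home <- function(home_id, config) {
  nd <- config$n_days
  dates <- config$start_date + seq_len(nd) - 1L
  nuis <- config$nuisance

  uti_days <- rep(FALSE, nd)
  if (!is.null(config$uti) && config$uti$n_episodes > 0) {
    starts <- config$uti$start_days
    if (is.null(starts)) {
      # spread episodes evenly through the period, away from the edges
      starts <- round(seq(0.2, 0.8, length.out = config$uti$n_episodes) * nd)
    }
    for (s in starts) {
      idx <- s:min(nd, s + config$uti$duration_days - 1L)
      uti_days[idx] <- TRUE
    }
  }
  disturbed_nights <- rep(FALSE, nd)
  if (!is.null(config$sleep_disturbance) && config$sleep_disturbance$n_nights > 0) {
    nights <- config$sleep_disturbance$nights
    if (is.null(nights)) {
      candidates <- which(!uti_days)
      nights <- sort(sample(candidates,
                            min(config$sleep_disturbance$n_nights, length(candidates))))
    }
    disturbed_nights[nights] <- TRUE
  }
  missing_days <- runif(nd) < nuis$missing_prob
  guest_days <- runif(nd) < nuis$guest_prob
  restless_nights <- !disturbed_nights & !uti_days & runif(nd) < nuis$restless_prob
  upset_days <- !uti_days & runif(nd) < (nuis$upset_day_prob %||% 0)

  ev <- vector("list", nd)
  vt <- vector("list", nd)
  for (d in seq_len(nd)) {
    day0 <- as.POSIXct(paste(dates[d], "00:00:00"), tz = "UTC")
    if (missing_days[d]) {
      ev[[d]] <- NULL           # whole-home technical outage: silent day
      vt[[d]] <- NULL
      next
    }
    day_bath_mult <- 1
    if (uti_days[d]) day_bath_mult <- config$uti$day_bathroom_multiplier %||% 1
    if (upset_days[d]) day_bath_mult <- runif(1, 3, 5)
    day_ev <- simulate_day_activity(day0, config, guest = guest_days[d],
                                    bath_mult = day_bath_mult)
    night_ev <- simulate_night(
      day0, config,
      uti = uti_days[d],
      wander_spec = night_wander_spec(config, uti_days[d], disturbed_nights[d],
                                      restless_nights[d])
    )
    ev[[d]] <- dplyr::bind_rows(day_ev, night_ev)
    vt[[d]] <- simulate_vitals_day(day0, config, uti = uti_days[d])
  }
  events <- dplyr::bind_rows(ev)
  vitals <- dplyr::bind_rows(vt)
  events$home_id <- home_id
  if (nrow(vitals)) vitals$home_id <- home_id
  labels <- tibble::tibble(
    home_id = home_id, date = dates,
    uti_episode = uti_days,
    sleep_disturbed = disturbed_nights,
    routine_anomaly = uti_days | disturbed_nights,
    excluded_night = missing_days
  )
  list(
    events = events[, c("home_id", "timestamp", "viewpoint", "state", "value")],
    vitals = if (nrow(vitals)) {
      vitals[, c("home_id", "timestamp", "parameter", "value")]
    } else {
      empty_records("vitals")
    },
    labels = labels
  )
}

# Per-minute activation rates by room during an out-of-bed bout. Wandering
# moves through the house; a sleepless spell settles in the living room.
bout_rates <- list(
  wander = c(hallway_pir = 0.15, kitchen_motion = 0.10, living_room_pir = 0.08),
  sleepless = c(hallway_pir = 0.05, living_room_pir = 0.15, chair_pressure = 0.04)
)

night_wander_spec <- function(config, uti, disturbed, restless) {
  if (disturbed) {
    sd <- config$sleep_disturbance
    list(bath_mult = 1, bouts = sd$bouts, bout_min = sd$bout_min,
         rates = bout_rates$wander)
  } else if (uti) {
    list(bath_mult = config$uti$bathroom_multiplier,
         bouts = config$uti$wander_bouts, bout_min = config$uti$wander_min,
         rates = bout_rates$wander)
  } else if (restless) {
    # benign irregular night, one of three characters: a short wandering
    # spell around the house, a long sleepless spell in the living room, or
    # a heavy-nocturia night (stomach upset, late fluids, diuretics)
    u <- runif(1)
    if (u < 1 / 3) {
      list(bath_mult = 1, bouts = sample(1:2, 1), bout_min = c(25, 45),
           rates = bout_rates$wander)
    } else if (u < 2 / 3) {
      list(bath_mult = 1, bouts = 1, bout_min = c(60, 120),
           rates = bout_rates$sleepless)
    } else {
      list(bath_mult = runif(1, 4, 6), bouts = 0)
    }
  } else {
    NULL
  }
}

# Poisson on-events for one viewpoint across the 24 hours of one day.
poisson_on_events <- function(day0, viewpoint, rates) {
  n <- rpois(24, rates)
  hours <- rep(0:23, n)
  if (!length(hours)) {
    return(NULL)
  }
  ts <- day0 + hours * 3600 + runif(length(hours)) * 3600
  tibble::tibble(
    timestamp = ts, viewpoint = viewpoint, state = "on", value = NA_real_
  )
}

simulate_day_activity <- function(day0, config, guest = FALSE,
                                  bath_mult = 1) {
  rates <- config$rate_profiles
  nuis <- config$nuisance
  guest_hours <- integer(0)
  if (guest) {
    start <- sample(10:16, 1)
    guest_hours <- start:(start + nuis$guest_hours - 1L)
  }
  out <- list()
  for (vp in names(rates)) {
    r <- rates[[vp]]
    if (vp %in% c("hallway_pir", "kitchen_motion", "living_room_pir")) {
      r <- r + nuis$pet_rate
    }
    if (vp == "bathroom_door_motion") r <- r * bath_mult
    if (guest && vp != "bed_pressure") {
      r[guest_hours + 1L] <- r[guest_hours + 1L] * nuis$guest_multiplier
    }
    if (vp == "chair_pressure") {
      out[[vp]] <- chair_epoch_events(day0, r)
    } else {
      out[[vp]] <- poisson_on_events(day0, vp, r)
    }
  }
  if (guest) {
    # extra door openings around arrival/departure
    t_arr <- day0 + guest_hours[1] * 3600 + runif(2) * 600
    t_dep <- day0 + (guest_hours[length(guest_hours)] + 1L) * 3600 - runif(2) * 600
    out$guest_door <- tibble::tibble(
      timestamp = c(t_arr, t_dep), viewpoint = "front_door",
      state = "on", value = NA_real_
    )
  }
  # hourly whole-home energy readings: base load + daytime activity
  watts <- 120 + ifelse(0:23 >= 7 & 0:23 < 23, 250, 0) + rnorm(24, 0, 30)
  out$energy <- tibble::tibble(
    timestamp = day0 + (0:23) * 3600 + 1800,
    viewpoint = "energy_monitor", state = "on", value = pmax(0, watts)
  )
  dplyr::bind_rows(out)
}

chair_epoch_events <- function(day0, rates) {
  n <- rpois(24, rates)
  hours <- rep(0:23, n)
  if (!length(hours)) {
    return(NULL)
  }
  t_on <- day0 + hours * 3600 + runif(length(hours)) * 3600
  dur <- runif(length(hours), 10, 40) * 60
  tibble::tibble(
    timestamp = c(t_on, t_on + dur),
    viewpoint = "chair_pressure",
    state = rep(c("on", "off"), each = length(t_on)),
    value = NA_real_
  )
}

# One night: bed-pressure occupancy epochs with turn-over blips, bathroom
# visits (out-of-bed epochs with bathroom/hallway activity) and optional
# wandering bouts around the house.
simulate_night <- function(day0, config, uti = FALSE, wander_spec = NULL) {
  bed <- config$bed
  entry <- day0 + bed$entry_hour * 3600 + rnorm(1, 0, bed$entry_sd_min * 60)
  sleep_len <- max(4 * 3600,
                   bed$sleep_hours * 3600 + rnorm(1, 0, bed$sleep_sd_min * 60))
  wake <- entry + sleep_len

  rate <- bed$bathroom_rate
  if (!is.null(wander_spec)) rate <- rate * (wander_spec$bath_mult %||% 1)
  n_visits <- rpois(1, rate)
  gaps <- list()
  bath_ev <- list()
  if (n_visits > 0) {
    starts <- sort(entry + 1800 + runif(n_visits) * (sleep_len - 3600))
    for (i in seq_len(n_visits)) {
      dur <- runif(1, bed$visit_min[1], bed$visit_min[2]) * 60
      gaps[[length(gaps) + 1L]] <- c(starts[i], starts[i] + dur)
      nb <- sample(2:3, 1)
      nh <- sample(1:2, 1)
      bath_ev[[length(bath_ev) + 1L]] <- tibble::tibble(
        timestamp = starts[i] + runif(nb + nh) * dur,
        viewpoint = c(rep("bathroom_door_motion", nb), rep("hallway_pir", nh)),
        state = "on", value = NA_real_
      )
    }
  }
  wander_ev <- list()
  if (!is.null(wander_spec) && wander_spec$bouts > 0) {
    for (b in seq_len(wander_spec$bouts)) {
      dur <- runif(1, wander_spec$bout_min[1], wander_spec$bout_min[2]) * 60
      start <- entry + 1800 + runif(1) * max(60, sleep_len - 3600 - dur)
      gaps[[length(gaps) + 1L]] <- c(start, start + dur)
      mins <- dur / 60
      rates <- wander_spec$rates
      counts <- rpois(length(rates), rates * mins)
      counts <- pmax(counts, c(2, rep(1, length(rates) - 1)))  # bout is active
      vps <- rep(names(rates), counts)
      wander_ev[[length(wander_ev) + 1L]] <- tibble::tibble(
        timestamp = start + runif(length(vps)) * dur,
        viewpoint = vps, state = "on", value = NA_real_
      )
    }
  }
  # turn-over blips: sub-minute bed-pressure gaps
  n_turn <- rpois(1, bed$turnover_rate)
  if (n_turn > 0) {
    t0 <- entry + runif(n_turn) * sleep_len
    for (i in seq_len(n_turn)) {
      gaps[[length(gaps) + 1L]] <- c(t0[i], t0[i] + runif(1, 20, 50))
    }
  }
  epochs <- occupancy_epochs(entry, wake, gaps)
  bed_ev <- tibble::tibble(
    timestamp = c(epochs$on, epochs$off),
    viewpoint = "bed_pressure",
    state = rep(c("on", "off"), each = length(epochs$on)),
    value = NA_real_
  )
  # bedroom door at bed entry and wake-up
  door_ev <- tibble::tibble(
    timestamp = c(entry - runif(1, 30, 120), wake + runif(1, 30, 120)),
    viewpoint = "bedroom_door_motion", state = "on", value = NA_real_
  )
  dplyr::bind_rows(c(list(bed_ev, door_ev), bath_ev, wander_ev))
}

# Subtract out-of-bed gaps from [entry, wake] giving on/off instants.
occupancy_epochs <- function(entry, wake, gaps) {
  if (!length(gaps)) {
    return(list(on = entry, off = wake))
  }
  g <- do.call(rbind, gaps)
  g <- g[order(g[, 1]), , drop = FALSE]
  g[, 1] <- pmax(g[, 1], entry)
  g[, 2] <- pmin(g[, 2], wake)
  g <- g[g[, 2] > g[, 1], , drop = FALSE]
  if (!nrow(g)) {
    return(list(on = entry, off = wake))
  }
  # merge overlapping gaps
  merged <- list(g[1, ])
  for (i in seq_len(nrow(g))[-1]) {
    last <- merged[[length(merged)]]
    if (g[i, 1] <= last[2]) {
      merged[[length(merged)]] <- c(last[1], max(last[2], g[i, 2]))
    } else {
      merged[[length(merged) + 1L]] <- g[i, ]
    }
  }
  m <- do.call(rbind, merged)
  on <- c(entry, m[, 2])
  off <- c(m[, 1], wake)
  keep <- off > on
  list(on = on[keep], off = off[keep])
}

simulate_vitals_day <- function(day0, config, uti = FALSE) {
  v <- config$vitals
  rows <- list()
  for (s in v$sessions) {
    ts <- day0 + s * 3600 + rnorm(1, 0, 15 * 60)
    for (p in vital_parameters()) {
      mu <- v[[p]][1]
      sdv <- v[[p]][2]
      if (uti && p == "body_temperature") {
        mu <- config$uti$temp_mean
        sdv <- config$uti$temp_sd
      }
      if (uti && p == "pulse") mu <- mu + 15
      val <- rnorm(1, mu, sdv)
      if (p == "spo2") val <- min(val, 100)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        timestamp = ts, parameter = p, value = max(0, val)
      )
    }
  }
  dplyr::bind_rows(rows)
}
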