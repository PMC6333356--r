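#' Pipeline configuration
#'
#' Parameters of the end-to-end run: a profiling period used to learn the
#' routine (default three months) followed by a test period scored by the
#' detectors. Every stochastic stage derives its seed from `seed`.
#'
#' @param seed Master seed (mandatory).
#' @param profile_days Length of the profiling split, default 90.
#' @param test_days Length of the test split, default 120.
#' @param uti_episodes Number of UTI episodes injected into the test split.
#' @param uti Overrides merged into the simulator's UTI spec.
#' @param disturbance_nights Sleep-disturbance nights injected into the test
#'   split.
#' @param fusion_window_hours Decision-fusion window, default 24.
#' @param temp_threshold Fever threshold in degrees C, default 38.
#' @param rank Fixed NMF rank (`NULL` = select per category).
#' @param xi_sleep,xi_dhs Deviation coefficients for sleep boundaries and the
#'   DHS interval.
#' @param dhs_window DHS trailing window `d`, default 14.
#' @param iforest_train_days Training days for the day estimator, default 30.
#' @param sim Additional overrides passed to [simulation_config()].
#' @return List of class `dws_pipeline_config`.
#' @export
pipeline_config <- function(seed,
                            profile_days = 90,
                            test_days = 120,
                            uti_episodes = 3,
                            uti = list(),
                            disturbance_nights = 8,
                            fusion_window_hours = 24,
                            temp_threshold = 38,
                            rank = NULL,
                            xi_sleep = 2,
                            xi_dhs = 1.96,
                            dhs_window = 14,
                            iforest_train_days = 30,
                            sim = list()) {
  if (missing(seed)) stop("a seed is mandatory")
  structure(
    list(seed = as.integer(seed), profile_days = profile_days,
         test_days = test_days, uti_episodes = uti_episodes, uti = uti,
         disturbance_nights = disturbance_nights,
         fusion_window_hours = fusion_window_hours,
         temp_threshold = temp_threshold, rank = rank,
         xi_sleep = xi_sleep, xi_dhs = xi_dhs, dhs_window = dhs_window,
         iforest_train_days = iforest_train_days, sim = sim),
    class = "dws_pipeline_config"
  )
}

#' Run the full monitoring pipeline on a simulated home
#'
#' Executes simulate, profile, detect (UTI fusion + daily anomaly),
#' explain (sleep + DHS) and evaluate in dependency order on one simulated
#' household. The profiling split learns the activity profile, the
#' isolation-forest scaling/training and the sleep boundaries; the test
#' split is scored. Identical config yields identical outputs.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, all artefacts (events,
#'   vitals, labels, alerts, nights, DHS, evaluation report, config) are
#'   written there as CSV/JSON.
#' @return List of class `dws_run`: `cohort`, `profile`, `uti_alerts`,
#'   `temp_alerts`, `rsfp_alerts`, `day_labels`, `nights`, `sleep_status`,
#'   `dhs`, `report`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "dws_pipeline_config"))
  n_days <- config$profile_days + config$test_days
  test_start_day <- config$profile_days + 1L

  uti_spec <- NULL
  if (config$uti_episodes > 0) {
    # episodes sit inside the test split, spread evenly
    starts <- test_start_day +
      round(seq(0.15, 0.75, length.out = config$uti_episodes) *
              config$test_days)
    uti_spec <- utils::modifyList(
      list(n_episodes = config$uti_episodes, start_days = starts),
      config$uti
    )
  }
  dist_spec <- NULL
  if (config$disturbance_nights > 0) {
    dist_spec <- list(n_nights = config$disturbance_nights)
  }
  sim_args <- utils::modifyList(
    list(n_homes = 1, n_days = n_days, seed = config$seed,
         uti = uti_spec, sleep_disturbance = dist_spec),
    config$sim
  )
  sim_cfg <- do.call(simulation_config, sim_args)
  # keep disturbance nights inside the test split
  if (!is.null(sim_cfg$sleep_disturbance) &&
      is.null(sim_cfg$sleep_disturbance$nights)) {
    sim_cfg$sleep_disturbance$nights <- with_local_seed(config$seed + 1L, {
      sort(sample(test_start_day:(n_days - 1L),
                  sim_cfg$sleep_disturbance$n_nights))
    })
  }
  cohort <- simulate_cohort(sim_cfg)

  d0 <- sim_cfg$start_date
  profile_end <- d0 + config$profile_days - 1L
  test_start <- d0 + config$profile_days
  test_end <- d0 + n_days - 1L
  home <- cohort$labels$home_id[1]

  # --- profile (routine learning) ---
  # k >= 3: with two clusters every size array gives both clusters the same
  # MAD score, so the three-way categorisation cannot separate them
  profile <- build_activity_profile(
    cohort, d0, profile_end, rank = config$rank, k_range = 3:10,
    seed = config$seed
  )

  # --- detect: UTI fusion ---
  test_windows <- build_sfp_windows(cohort, test_start, test_end)
  rsfp <- rsfp_alerts(test_windows, profile, home_id = home)
  vit <- cohort$vitals
  vit_test <- vit[wallclock_date(vit$timestamp) >= test_start, , drop = FALSE]
  temp <- temperature_alerts(vit_test, threshold = config$temp_threshold)
  uti <- fuse_decisions(temp, rsfp, window_hours = config$fusion_window_hours)

  # --- detect: daily anomaly ---
  train_end <- d0 + config$iforest_train_days - 1L
  daily_train <- build_daily_matrices(cohort, d0, train_end)
  daily_test <- build_daily_matrices(
    cohort, test_start, test_end,
    train_start = d0, train_end = train_end
  )
  day_labels <- fit_and_label(daily_train, daily_test, seed = config$seed)

  # --- explain: sleep ---
  profile_nights <- analyse_sleep(cohort, seq(d0, profile_end - 1L, by = "day"))
  bounds <- adaptive_boundaries(profile_nights, xi = config$xi_sleep,
                                min_history = min(30, config$profile_days - 1))
  test_nights <- analyse_sleep(cohort, seq(test_start, test_end - 1L, by = "day"))
  sleep_status <- vapply(test_nights, detect_disturbance, character(1),
                         bounds = bounds)
  nights_tab <- summarise_nights(test_nights)
  nights_tab$status <- sleep_status

  # --- explain: DHS ---
  dhs <- daily_health_score(cohort)
  dhs$flag <- FALSE
  if (nrow(dhs) > config$dhs_window) {
    iv <- adaptive_interval(dhs$total, d = config$dhs_window, xi = config$xi_dhs)
    dhs$flag[as.integer(names(iv$flags))] <- iv$flags
  }

  # --- evaluate against ground truth ---
  labels <- cohort$labels
  test_labels <- labels[labels$date >= test_start, , drop = FALSE]
  uti_eval <- evaluate_uti_alerts(uti, labels)
  sleep_eval <- evaluate_sleep_status(nights_tab, labels)
  anomaly_eval <- evaluate_day_scores(day_labels$labels, labels)
  report <- list(
    uti = uti_eval, sleep = sleep_eval, daily_anomaly = anomaly_eval,
    seed = config$seed,
    n_test_days = nrow(test_labels)
  )
  run <- structure(
    list(cohort = cohort, profile = profile, uti_alerts = uti,
         temp_alerts = temp, rsfp_alerts = rsfp, day_labels = day_labels,
         nights = test_nights, sleep_status = nights_tab, dhs = dhs,
         report = report, config = config),
    class = "dws_run"
  )
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

#' Evaluate fused UTI alerts against injected episodes
#'
#' An episode counts as detected when at least one fused alert falls on an
#' episode day or the day after (night activity of an episode's last
#' evening spills past midnight). Alert days outside every such span are
#' false alert days.
#'
#' @param alerts Fused alert tibble from [fuse_decisions()].
#' @param labels Ground-truth label tibble with `date` and `uti_episode`.
#' @return List: `n_episodes`, `n_detected`, `alert_days`,
#'   `non_episode_alert_days`.
#' @export
evaluate_uti_alerts <- function(alerts, labels) {
  epi_days <- labels$date[labels$uti_episode]
  # group consecutive episode days into episodes
  episodes <- split(epi_days, cumsum(c(1, diff(epi_days) > 1)))
  alert_days <- unique(wallclock_date(alerts$timestamp))
  tol_days <- unique(c(epi_days, epi_days + 1))
  detected <- vapply(episodes, function(days) {
    any(alert_days %in% c(days, max(days) + 1))
  }, logical(1))
  list(
    n_episodes = length(episodes),
    n_detected = sum(detected),
    alert_days = length(alert_days),
    non_episode_alert_days = sum(!(alert_days %in% tol_days))
  )
}

#' Evaluate sleep-disturbance calls against injected nights
#'
#' @param nights_tab [summarise_nights()] tibble with a `status` column.
#' @param labels Ground-truth label tibble (`date`, `sleep_disturbed`).
#' @return List: confusion counts and `rho_sen`, `rho_spe`, `rho`.
#' @export
evaluate_sleep_status <- function(nights_tab, labels) {
  m <- merge(nights_tab, labels[, c("date", "sleep_disturbed")], by = "date")
  m <- m[m$status != "excluded", , drop = FALSE]
  cc <- confusion_counts(
    predicted = ifelse(m$status == "disturbed", "positive", "negative"),
    reference = ifelse(m$sleep_disturbed, "positive", "negative")
  )
  c(cc, confusion_metrics(cc$tp, cc$fp, cc$fn, cc$tn))
}

#' Evaluate day anomaly scores against injected anomalous days
#'
#' Measures whether the injected anomalous days (ground-truth
#' `routine_anomaly`) rank among the top scores. Night-time injections
#' straddle midnight, so each anomalous date is credited with the better
#' rank of itself and the following day.
#'
#' @param day_labels Label tibble from [fit_and_label()].
#' @param labels Ground-truth label tibble.
#' @return List: `n_anomalous`, `n_scored`, `top5pct_hits` (how many
#'   injected days rank in the top 5% of scores), `anomalous_ranks`.
#' @export
evaluate_day_scores <- function(day_labels, labels) {
  m <- merge(day_labels, labels[, c("date", "routine_anomaly", "excluded_night")],
             by = "date")
  m <- m[!m$excluded_night, , drop = FALSE]
  m$rank <- rank(-m$score, ties.method = "min")
  k <- max(1L, floor(0.05 * nrow(m)))
  best <- vapply(m$date[m$routine_anomaly], function(d) {
    min(m$rank[m$date %in% c(d, d + 1)])
  }, numeric(1))
  list(
    n_anomalous = sum(m$routine_anomaly),
    n_scored = nrow(m),
    top5pct_hits = sum(best <= k),
    anomalous_ranks = sort(best)
  )
}

write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_records(run$cohort$events, file.path(out_dir, "events.csv"))
  write_records(run$cohort$vitals, file.path(out_dir, "vitals.csv"))
  readr::write_csv(run$cohort$labels, file.path(out_dir, "labels.csv"),
                   progress = FALSE)
  al <- run$uti_alerts
  al$timestamp <- format(al$timestamp, "%Y-%m-%d %H:%M:%S", tz = "UTC")
  al$temp_time <- format(al$temp_time, "%Y-%m-%d %H:%M:%S", tz = "UTC")
  al$rsfp_time <- format(al$rsfp_time, "%Y-%m-%d %H:%M:%S", tz = "UTC")
  readr::write_csv(al, file.path(out_dir, "uti_alerts.csv"), progress = FALSE)
  readr::write_csv(run$sleep_status, file.path(out_dir, "nights.csv"),
                   progress = FALSE)
  readr::write_csv(run$dhs, file.path(out_dir, "dhs.csv"), progress = FALSE)
  readr::write_csv(run$day_labels$labels, file.path(out_dir, "day_labels.csv"),
                   progress = FALSE)
  jsonlite::write_json(run$report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  cfg <- run$config
  class(cfg) <- NULL
  yaml::write_yaml(cfg, file.path(out_dir, "config.yaml"))
  invisible(out_dir)
}

#' @export
print.dws_run <- function(x, ...) {
  r <- x$report
  cat("<dws_run> seed ", x$config$seed, "\n", sep = "")
  cat(sprintf("  UTI: %d/%d episodes detected, %d non-episode alert day(s)\n",
              r$uti$n_detected, r$uti$n_episodes, r$uti$non_episode_alert_days))
  cat(sprintf("  sleep: sens %.2f spec %.2f acc %.2f\n",
              r$sleep$rho_sen, r$sleep$rho_spe, r$sleep$rho))
  cat(sprintf("  daily anomaly: %d/%d injected days in top 5%%\n",
              r$daily_anomaly$top5pct_hits, r$daily_anomaly$n_anomalous))
  invisible(x)
}
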