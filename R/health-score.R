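#' Score a single vital-sign parameter
#'
#' Banded early-warning scores for the four parameters of the daily health
#' score, following the NEWS2-derived banding:
#'
#' | parameter | 3 | 2 | 1 | 0 | 1 | 2 | 3 |
#' |---|---|---|---|---|---|---|---|
#' | systolic (mmHg) | <=90 | 91-100 | 101-110 | 111-219 | | | >=220 |
#' | pulse (/min) | <=40 | | 41-50 | 51-90 | 91-110 | 111-130 | >=131 |
#' | temperature (C) | <=35 | | 35.1-36 | 36.1-38 | 38.1-39 | >=39.1 | |
#' | SpO2 (%) | <=91 | 92-93 | 94-95 | >=96 | | | |
#'
#' Values are rounded to the band precision before lookup (0.1 C for
#' temperature, whole units otherwise), which closes the gaps between
#' printed band edges.
#'
#' @param parameter One of `"systolic_bp"`, `"pulse"`, `"body_temperature"`,
#'   `"spo2"`.
#' @param value Finite numeric value(s).
#' @return Integer score(s) in `{0, 1, 2, 3}`.
#' @export
score_parameter <- function(parameter, value) {
  parameter <- match.arg(parameter,
                         c("systolic_bp", "pulse", "body_temperature", "spo2"))
  stopifnot(all(is.finite(value)))
  vapply(value, function(v) score_one(parameter, v), integer(1))
}

score_one <- function(parameter, v) {
  if (parameter == "body_temperature") {
    v <- round_half_up(v, 1)
    if (v <= 35) return(3L)
    if (v <= 36) return(1L)
    if (v <= 38) return(0L)
    if (v <= 39) return(1L)
    return(2L)
  }
  v <- round_half_up(v, 0)
  switch(parameter,
    systolic_bp = {
      if (v <= 90) 3L
      else if (v <= 100) 2L
      else if (v <= 110) 1L
      else if (v <= 219) 0L
      else 3L
    },
    pulse = {
      if (v <= 40) 3L
      else if (v <= 50) 1L
      else if (v <= 90) 0L
      else if (v <= 110) 1L
      else if (v <= 130) 2L
      else 3L
    },
    spo2 = {
      if (v <= 91) 3L
      else if (v <= 93) 2L
      else if (v <= 95) 1L
      else 0L
    }
  )
}

#' Daily health score
#'
#' Computes the daily health score (DHS) per home-day from vitals readings.
#' Readings are grouped into measurement sessions (before/after 14:00,
#' matching the twice-daily cadence); within a session the four scored
#' parameters are banded with [score_parameter()] and summed (missing
#' parameters contribute 0 and are recorded); the day's DHS is the maximum
#' session total — the worst observation of the day. Days with no scored
#' parameter produce no record.
#'
#' @param vitals Vitals tibble (or `dws_stream` / `dws_cohort`).
#' @return Tibble: `home_id`, `date`, `score_systolic`, `score_pulse`,
#'   `score_temp`, `score_spo2` (components of the worst session), `total`,
#'   `missing` (comma-separated absent parameters of that session).
#' @export
daily_health_score <- function(vitals) {
  if (inherits(vitals, "dws_stream")) vitals <- vitals$records
  if (inherits(vitals, "dws_cohort")) vitals <- vitals$vitals
  scored <- c("systolic_bp", "pulse", "body_temperature", "spo2")
  v <- vitals[vitals$parameter %in% scored, , drop = FALSE]
  if (!nrow(v)) {
    return(tibble::tibble(
      home_id = character(), date = as.Date(character()),
      score_systolic = integer(), score_pulse = integer(),
      score_temp = integer(), score_spo2 = integer(),
      total = integer(), missing = character()
    ))
  }
  v$date <- wallclock_date(v$timestamp)
  v$session <- ifelse(wallclock_hour(v$timestamp) < 14, "am", "pm")
  keys <- unique(v[, c("home_id", "date")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    vi <- v[v$home_id == keys$home_id[i] & v$date == keys$date[i], , drop = FALSE]
    best <- NULL
    for (s in unique(vi$session)) {
      vs <- vi[vi$session == s, , drop = FALSE]
      sc <- stats::setNames(integer(4), scored)
      present <- stats::setNames(logical(4), scored)
      for (p in scored) {
        val <- vs$value[vs$parameter == p]
        if (length(val)) {
          sc[p] <- score_parameter(p, val[length(val)])
          present[p] <- TRUE
        }
      }
      cand <- list(scores = sc, total = sum(sc),
                   missing = paste(scored[!present], collapse = ","))
      if (is.null(best) || cand$total > best$total) best <- cand
    }
    tibble::tibble(
      home_id = keys$home_id[i], date = keys$date[i],
      score_systolic = best$scores[["systolic_bp"]],
      score_pulse = best$scores[["pulse"]],
      score_temp = best$scores[["body_temperature"]],
      score_spo2 = best$scores[["spo2"]],
      total = as.integer(best$total),
      missing = best$missing
    )
  })
  out <- dplyr::bind_rows(rows)
  dplyr::arrange(out, .data$home_id, .data$date)
}

#' Adaptive personal DHS confidence interval
#'
#' Computes the personal band `mu +/- xi * sigma`, with `mu` and `sigma`
#' the mean and sample standard deviation of the DHS over the trailing `d`
#' days of history (default `d = 14`). When the history is longer than `d`,
#' every later day is additionally flagged against the interval of the `d`
#' days preceding it (a rolling personal band); a day exceeds when its DHS
#' is strictly greater than the upper bound.
#'
#' @param history Numeric vector of daily DHS totals, oldest first
#'   (length >= `d`).
#' @param d Window length in days, default 14.
#' @param xi Confidence coefficient, default 1.96.
#' @return List of class `dws_interval`: `mu`, `sigma`, `xi`, `d`, `lower`,
#'   `upper` (from the trailing `d` days), and `flags` (logical, one per
#'   history day after the first `d`).
#' @export
adaptive_interval <- function(history, d = 14, xi = 1.96) {
  history <- as.numeric(history)
  if (length(history) < d) {
    stop("need at least d = ", d, " days of history")
  }
  win <- utils::tail(history, d)
  mu <- mean(win)
  sigma <- sd(win)
  flags <- logical(0)
  if (length(history) > d) {
    idx <- (d + 1):length(history)
    flags <- vapply(idx, function(i) {
      w <- history[(i - d):(i - 1)]
      history[i] > mean(w) + xi * sd(w)
    }, logical(1))
    names(flags) <- idx
  }
  structure(
    list(mu = mu, sigma = sigma, xi = xi, d = d,
         lower = mu - xi * sigma, upper = mu + xi * sigma, flags = flags),
    class = "dws_interval"
  )
}

#' Does a new day exceed the personal interval?
#'
#' @param interval A [adaptive_interval()].
#' @param value New-day DHS value(s).
#' @return Logical: strictly above the upper bound.
#' @export
exceeds_interval <- function(interval, value) {
  value > interval$upper
}
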