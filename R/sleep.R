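#' AASM-derived stage thresholds
#'
#' Temporal thresholds of the rule engine, taken from published adult sleep
#' stage durations: N1 lasts 1-7 minutes, N2 10-25, N3 20-40, and a full
#' sleep cycle 90-100 minutes. Derived rules: sleep onset requires an in-bed
#' epoch longer than `mean(N1_L + N2_L, N1_H + N2_H) = 21.5` minutes;
#' an in-bed epoch shorter than `N1_L + N2_L = 11` minutes is restless; an
#' epoch of at least one full cycle (90 minutes) is good sleep.
#'
#' @param n1 N1 duration range (minutes).
#' @param n2 N2 duration range.
#' @param n3 N3 duration range.
#' @param cycle_min Full sleep-cycle minimum (minutes).
#' @return List of class `dws_stage_thresholds` with the ranges plus the
#'   derived `onset_min` and `restless_max`.
#' @export
stage_thresholds <- function(n1 = c(1, 7), n2 = c(10, 25), n3 = c(20, 40),
                             cycle_min = 90) {
  stopifnot(n1[1] < n1[2], n2[1] < n2[2], n3[1] < n3[2], cycle_min > 0)
  structure(
    list(
      n1 = n1, n2 = n2, n3 = n3, cycle_min = cycle_min,
      onset_min = mean(c(n1[1] + n2[1], n1[2] + n2[2])),
      restless_max = n1[1] + n2[1]
    ),
    class = "dws_stage_thresholds"
  )
}

#' Extract raw bed epochs for one night
#'
#' Pairs bed-pressure on/off transitions inside the night window, defined as
#' 18:00 of `night_date` to 12:00 the next day (wide enough that the
#' occupant is out of bed at both ends).
#'
#' @param events Event tibble (or `dws_stream` / `dws_cohort`) for one home.
#' @param night_date Date on whose evening the night begins.
#' @return Tibble of raw occupied epochs: `onset`, `offset`, `tau_min`
#'   (duration), `delta_min` (gap to the next epoch, NA for the last), with
#'   attributes `window_start`/`window_end`.
#' @export
extract_bed_epochs <- function(events, night_date) {
  if (inherits(events, "dws_stream")) events <- events$records
  if (inherits(events, "dws_cohort")) events <- events$events
  night_date <- as.Date(night_date)
  w0 <- as.POSIXct(paste(night_date, "18:00:00"), tz = "UTC")
  w1 <- w0 + 18 * 3600  # next day 12:00
  bed <- events[events$viewpoint == "bed_pressure" &
                  events$timestamp >= w0 & events$timestamp < w1, , drop = FALSE]
  bed <- bed[order(bed$timestamp), , drop = FALSE]
  on_t <- bed$timestamp[bed$state == "on"]
  off_t <- bed$timestamp[bed$state == "off"]
  eps <- list()
  for (o in as.numeric(on_t)) {
    nxt <- off_t[as.numeric(off_t) > o]
    if (!length(nxt)) break
    eps[[length(eps) + 1L]] <- c(o, as.numeric(min(nxt)))
  }
  if (length(eps)) {
    m <- do.call(rbind, eps)
    m <- m[!duplicated(m[, 2]), , drop = FALSE]  # one epoch per off transition
    out <- tibble::tibble(
      onset = as.POSIXct(m[, 1], origin = "1970-01-01", tz = "UTC"),
      offset = as.POSIXct(m[, 2], origin = "1970-01-01", tz = "UTC")
    )
  } else {
    out <- tibble::tibble(
      onset = as.POSIXct(character(), tz = "UTC"),
      offset = as.POSIXct(character(), tz = "UTC")
    )
  }
  out$tau_min <- as.numeric(difftime(out$offset, out$onset, units = "mins"))
  out$delta_min <- c(
    as.numeric(difftime(out$onset[-1], out$offset[-nrow(out)], units = "mins")),
    NA_real_
  )[seq_len(nrow(out))]
  attr(out, "window_start") <- w0
  attr(out, "window_end") <- w1
  attr(out, "night_date") <- night_date
  out
}

#' First-level rules: definitive in-bed / out-of-bed epochs
#'
#' Cleans raw occupied epochs into strictly alternating definitive in-bed
#' and out-of-bed epochs: occupancy gaps shorter than `delta_merge` minutes
#' (turning over in bed) are merged into continuous in-bed epochs, then
#' isolated occupied blips shorter than `tau_min` minutes (sitting down
#' briefly) are removed.
#'
#' @param raw Output of [extract_bed_epochs()] (or a tibble with
#'   `onset`/`offset`).
#' @param tau_min Minimum in-bed epoch length to keep, minutes (default 1).
#' @param delta_merge Maximum gap to merge, minutes (default 2).
#' @return Tibble of class `dws_bed_epochs`: alternating `state`
#'   ("in"/"out") with `start`, `end`, `dur_min`; empty (with attribute
#'   `away = TRUE`) when there are no bed events at all.
#' @export
preprocess_bed_epochs <- function(raw, tau_min = 1, delta_merge = 2) {
  empty <- tibble::tibble(
    state = character(),
    start = as.POSIXct(character(), tz = "UTC"),
    end = as.POSIXct(character(), tz = "UTC"),
    dur_min = numeric()
  )
  if (!nrow(raw)) {
    attr(empty, "away") <- TRUE
    class(empty) <- c("dws_bed_epochs", class(empty))
    return(empty)
  }
  raw <- raw[order(raw$onset), , drop = FALSE]
  # merge short gaps
  on <- as.numeric(raw$onset)
  off <- as.numeric(raw$offset)
  m_on <- on[1]
  m_off <- off[1]
  merged <- list()
  for (i in seq_along(on)[-1]) {
    gap_min <- (on[i] - m_off[length(m_off)]) / 60
    if (gap_min < delta_merge) {
      m_off[length(m_off)] <- max(m_off[length(m_off)], off[i])
    } else {
      m_on <- c(m_on, on[i])
      m_off <- c(m_off, off[i])
    }
  }
  keep <- (m_off - m_on) / 60 >= tau_min
  m_on <- m_on[keep]
  m_off <- m_off[keep]
  if (!length(m_on)) {
    attr(empty, "away") <- TRUE
    class(empty) <- c("dws_bed_epochs", class(empty))
    return(empty)
  }
  st <- character(0)
  s <- numeric(0)
  e <- numeric(0)
  for (i in seq_along(m_on)) {
    if (i > 1) {
      st <- c(st, "out")
      s <- c(s, m_off[i - 1])
      e <- c(e, m_on[i])
    }
    st <- c(st, "in")
    s <- c(s, m_on[i])
    e <- c(e, m_off[i])
  }
  out <- tibble::tibble(
    state = st,
    start = as.POSIXct(s, origin = "1970-01-01", tz = "UTC"),
    end = as.POSIXct(e, origin = "1970-01-01", tz = "UTC"),
    dur_min = (e - s) / 60
  )
  attr(out, "away") <- FALSE
  for (a in c("window_start", "window_end", "night_date")) {
    attr(out, a) <- attr(raw, a)
  }
  class(out) <- c("dws_bed_epochs", class(out))
  out
}

#' Second-level rules: label the night's sleep states
#'
#' Applies the temporal rules to the definitive epochs together with ambient
#' (non-bed) events in the night window:
#'
#' * sleep onset = start of the first in-bed epoch longer than
#'   `thr$onset_min` (21.5 min by default); offset = end of the last such
#'   epoch;
#' * in-bed epochs between onset and offset: shorter than
#'   `thr$restless_max` (11 min) = `restless`; at least `thr$cycle_min`
#'   (90 min, one full cycle) = `sleep_good`; otherwise `sleep_moderate`;
#' * out-of-bed epochs between onset and offset: `wandering` when at least
#'   `w_min` ambient activations on at least two distinct non-bedroom
#'   viewpoints fall inside the epoch, else `out_of_bed`.
#'
#' Validity: a night with no bed epochs is `away`; onset never reached or
#' total in-bed time under 3 hours is `short_sleep`; an all-sensor silence
#' of 6 hours or more inside the night window is `technical`.
#'
#' @param clean A `dws_bed_epochs` from [preprocess_bed_epochs()].
#' @param ambient Event tibble for the same home (all viewpoints; bed and
#'   bedroom channels are ignored for the wandering rule).
#' @param thr [stage_thresholds()].
#' @param w_min Minimum ambient activations for wandering (default 3).
#' @return Object of class `dws_night`: `date`, `valid`, `reason`
#'   (`"valid"`, `"away"`, `"short_sleep"`, `"technical"`), `onset`,
#'   `offset`, `blocks` (tibble `state`, `start`, `end`, `dur_min`) and
#'   per-state total minutes (`sleep_min`, `restless_min`, `wandering_min`,
#'   `out_of_bed_min`).
#' @export
label_sleep_states <- function(clean, ambient = NULL,
                               thr = stage_thresholds(), w_min = 3) {
  night_date <- attr(clean, "night_date")
  w0 <- attr(clean, "window_start")
  w1 <- attr(clean, "window_end")
  if (inherits(ambient, "dws_stream")) ambient <- ambient$records
  if (inherits(ambient, "dws_cohort")) ambient <- ambient$events

  res <- function(valid, reason, onset = NULL, offset = NULL,
                  blocks = NULL) {
    blocks <- blocks %||% tibble::tibble(
      state = character(), start = as.POSIXct(character(), tz = "UTC"),
      end = as.POSIXct(character(), tz = "UTC"), dur_min = numeric()
    )
    tot <- function(states) sum(blocks$dur_min[blocks$state %in% states])
    structure(
      list(
        date = night_date, valid = valid, reason = reason,
        onset = onset, offset = offset, blocks = blocks,
        sleep_min = tot(c("sleep_good", "sleep_moderate")),
        restless_min = tot("restless"),
        wandering_min = tot("wandering"),
        out_of_bed_min = tot("out_of_bed")
      ),
      class = "dws_night"
    )
  }

  if (isTRUE(attr(clean, "away")) || !nrow(clean)) {
    return(res(FALSE, "away"))
  }
  # technical exclusion: >= 6 h with no events from any sensor in-window
  if (!is.null(ambient) && !is.null(w0)) {
    amb_w <- ambient[ambient$timestamp >= w0 & ambient$timestamp < w1, ,
                     drop = FALSE]
    # gaps up to the last observed event only: silence after the final
    # wake-up is indistinguishable from an ordinary morning out of the house.
    # Silence during a continuous in-bed epoch is expected (the mat is a
    # level sensor), so only out-of-bed silence counts.
    instants <- sort(unique(c(as.numeric(w0), as.numeric(amb_w$timestamp),
                              as.numeric(clean$start), as.numeric(clean$end))))
    inbed_ep <- clean[clean$state == "in", , drop = FALSE]
    if (length(instants) > 1) {
      a <- utils::head(instants, -1)
      b <- instants[-1]
      mid <- (a + b) / 2
      covered <- vapply(mid, function(t) {
        any(t >= as.numeric(inbed_ep$start) & t < as.numeric(inbed_ep$end))
      }, logical(1))
      if (any((b - a)[!covered] >= 6 * 3600)) {
        return(res(FALSE, "technical"))
      }
    }
  }
  inbed <- clean[clean$state == "in", , drop = FALSE]
  big <- inbed$dur_min > thr$onset_min
  if (!any(big)) {
    return(res(FALSE, "short_sleep"))
  }
  onset <- inbed$start[which(big)[1]]
  offset <- inbed$end[which(big)[sum(big)]]
  span <- clean[clean$start >= onset & clean$end <= offset, , drop = FALSE]
  total_inbed <- sum(span$dur_min[span$state == "in"])
  if (total_inbed < 180) {
    return(res(FALSE, "short_sleep"))
  }

  amb <- NULL
  if (!is.null(ambient)) {
    amb <- ambient[
      !(ambient$viewpoint %in% c("bed_pressure", "bedroom_door_motion")) &
        (is.na(ambient$state) | ambient$state == "on"), , drop = FALSE]
  }
  lab <- character(nrow(span))
  for (i in seq_len(nrow(span))) {
    if (span$state[i] == "in") {
      d <- span$dur_min[i]
      lab[i] <- if (d < thr$restless_max) {
        "restless"
      } else if (d >= thr$cycle_min) {
        "sleep_good"
      } else {
        "sleep_moderate"
      }
    } else {
      n_act <- 0L
      n_vp <- 0L
      if (!is.null(amb)) {
        hit <- amb$timestamp >= span$start[i] & amb$timestamp < span$end[i]
        n_act <- sum(hit)
        n_vp <- length(unique(amb$viewpoint[hit]))
      }
      lab[i] <- if (n_act >= w_min && n_vp >= 2) "wandering" else "out_of_bed"
    }
  }
  blocks <- tibble::tibble(
    state = lab, start = span$start, end = span$end, dur_min = span$dur_min
  )
  res(TRUE, "valid", onset = onset, offset = offset, blocks = blocks)
}

#' @export
print.dws_night <- function(x, ...) {
  cat("<dws_night> ", format(x$date), " ", x$reason, sep = "")
  if (x$valid) {
    cat(sprintf(
      ": sleep %.0f min, restless %.0f, wandering %.0f, out-of-bed %.0f",
      x$sleep_min, x$restless_min, x$wandering_min, x$out_of_bed_min
    ))
  }
  cat("\n")
  invisible(x)
}

#' Analyse a sequence of nights
#'
#' Convenience wrapper: extracts, cleans and labels one night per date.
#'
#' @param events Event tibble (or `dws_stream` / `dws_cohort`) for one home.
#' @param night_dates Dates on whose evenings the nights begin.
#' @param thr,w_min,tau_min,delta_merge Rule parameters.
#' @return List of `dws_night` objects.
#' @export
analyse_sleep <- function(events, night_dates, thr = stage_thresholds(),
                          w_min = 3, tau_min = 1, delta_merge = 2) {
  if (inherits(events, "dws_stream")) events <- events$records
  if (inherits(events, "dws_cohort")) events <- events$events
  lapply(as.list(as.Date(night_dates)), function(d) {
    raw <- extract_bed_epochs(events, d)
    clean <- preprocess_bed_epochs(raw, tau_min = tau_min,
                                   delta_merge = delta_merge)
    label_sleep_states(clean, ambient = events, thr = thr, w_min = w_min)
  })
}

#' Summarise nights into a tibble
#'
#' @param nights List of `dws_night` objects.
#' @return Tibble with one row per night: `date`, `valid`, `reason`,
#'   `sleep_min`, `restless_min`, `wandering_min`, `out_of_bed_min`.
#' @export
summarise_nights <- function(nights) {
  dplyr::bind_rows(lapply(nights, function(n) {
    tibble::tibble(
      date = n$date, valid = n$valid, reason = n$reason,
      sleep_min = n$sleep_min, restless_min = n$restless_min,
      wandering_min = n$wandering_min, out_of_bed_min = n$out_of_bed_min
    )
  }))
}

#' Adaptive personal sleep deviation boundaries
#'
#' From at least `min_history` valid nights, computes the personal minimum
#' sleep duration `mu_sleep - xi * sigma_sleep` and maximum
#' restless-plus-wandering duration `mu_rw + xi * sigma_rw`.
#'
#' @param nights List of `dws_night` objects or a [summarise_nights()] tibble.
#' @param xi Deviation coefficient, default 2 (about the 95th percentile
#'   under normality).
#' @param min_history Required number of valid nights, default 30.
#' @return List of class `dws_sleep_bounds`: `min_sleep_min`, `max_rw_min`,
#'   and the `mu`/`sigma`/`xi`/`n` used.
#' @export
adaptive_boundaries <- function(nights, xi = 2, min_history = 30) {
  tab <- if (inherits(nights, "data.frame")) nights else summarise_nights(nights)
  tab <- tab[tab$valid, , drop = FALSE]
  if (nrow(tab) < min_history) {
    stop("need at least ", min_history, " valid nights (have ", nrow(tab), ")")
  }
  rw <- tab$restless_min + tab$wandering_min
  structure(
    list(
      min_sleep_min = mean(tab$sleep_min) - xi * sd(tab$sleep_min),
      max_rw_min = mean(rw) + xi * sd(rw),
      mu_sleep = mean(tab$sleep_min), sigma_sleep = sd(tab$sleep_min),
      mu_rw = mean(rw), sigma_rw = sd(rw),
      xi = xi, n = nrow(tab)
    ),
    class = "dws_sleep_bounds"
  )
}

#' Detect a sleep disturbance
#'
#' Classifies a labelled night against the personal boundaries: `excluded`
#' when the night is invalid (away, under three hours in bed, technical
#' gap); `disturbed` when sleep duration falls below the personal minimum or
#' restless-plus-wandering time exceeds the personal maximum; otherwise
#' `normal`.
#'
#' @param night A `dws_night`.
#' @param bounds A [adaptive_boundaries()] result.
#' @return One of `"normal"`, `"disturbed"`, `"excluded"`.
#' @export
detect_disturbance <- function(night, bounds) {
  if (!night$valid) {
    return("excluded")
  }
  rw <- night$restless_min + night$wandering_min
  if (night$sleep_min < bounds$min_sleep_min || rw > bounds$max_rw_min) {
    "disturbed"
  } else {
    "normal"
  }
}
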