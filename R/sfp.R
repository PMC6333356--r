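#' Time-of-day category of an instant
#'
#' Maps wall-clock instants to the four six-hour categories used for
#' activity profiling: night \[00:00, 06:00), morning \[06:00, 12:00),
#' afternoon \[12:00, 18:00), evening \[18:00, 24:00).
#'
#' @param timestamp POSIXct vector (naive local wall-clock time).
#' @return Character vector of categories.
#' @export
time_category_of <- function(timestamp) {
  h <- wallclock_hour(as_wallclock(timestamp))
  c("night", "morning", "afternoon", "evening")[h %/% 6 + 1L]
}

# Fixed flattening order of a 6x8 window: hour-major, i.e. entries 1..8 are
# the eight viewpoints of the window's first hour, 9..16 its second hour, ...
sfp_feature_names <- function() {
  as.vector(t(outer(0:5, sfp_viewpoints(), function(h, v) paste0("h", h, "_", v))))
}

#' Flatten / unflatten a six-hour SFP window
#'
#' A six-hour SFP window is a 6 (hours) x 8 (viewpoints) count matrix; the
#' flattened form is the 48-vector in fixed hour-major order (all eight
#' viewpoints of hour 1, then hour 2, ...), the column layout of the data
#' matrix fed to the NMF. The two functions are exact inverses.
#'
#' @param counts 6x8 matrix (`flatten_sfp`) or 48-vector (`unflatten_sfp`).
#' @return 48-vector, or 6x8 matrix with dimnames.
#' @export
flatten_sfp <- function(counts) {
  stopifnot(is.matrix(counts), nrow(counts) == 6, ncol(counts) == 8)
  stats::setNames(as.vector(t(counts)), sfp_feature_names())
}

#' @rdname flatten_sfp
#' @export
unflatten_sfp <- function(counts) {
  stopifnot(length(counts) == 48)
  m <- matrix(counts, nrow = 6, ncol = 8, byrow = TRUE)
  dimnames(m) <- list(paste0("h", 0:5), sfp_viewpoints())
  m
}

#' Build six-hour sensor firing pattern windows
#'
#' Aggregates activation events on the eight profiling viewpoints into
#' per-hour counts, concatenates hours into six-hour windows aligned at
#' 00:00/06:00/12:00/18:00, and groups the flattened windows by time
#' category into one 48 x n data matrix per category (columns chronological,
#' one per window). Windows with no events are retained as zero matrices.
#' Only `state == "on"` activations are counted.
#'
#' @param events Event tibble (or `dws_stream`) for a single home.
#' @param period_start,period_end Date range (inclusive) to aggregate.
#' @param categories Categories to return; default all four.
#' @return List of class `dws_sfp_set`: `windows` (tibble with `window_start`,
#'   `category` and a list-column `counts` of 6x8 matrices), `matrices`
#'   (named list of 48 x n matrices per category), `n_outside` (count of
#'   events outside the period).
#' @export
build_sfp_windows <- function(events, period_start, period_end,
                              categories = time_categories()) {
  if (inherits(events, "dws_stream")) events <- events$records
  if (inherits(events, "dws_cohort")) events <- events$events
  period_start <- as.Date(period_start)
  period_end <- as.Date(period_end)
  if (period_end < period_start) stop("empty period")
  categories <- match.arg(categories, time_categories(), several.ok = TRUE)
  if (length(unique(events$home_id)) > 1) {
    stop("build_sfp_windows expects events from a single home")
  }

  vps <- sfp_viewpoints()
  ev <- events[events$viewpoint %in% vps &
                 (is.na(events$state) | events$state == "on"), , drop = FALSE]
  ev_dates <- wallclock_date(ev$timestamp)
  inside <- ev_dates >= period_start & ev_dates <= period_end
  n_outside <- sum(!inside)
  ev <- ev[inside, , drop = FALSE]

  days <- seq(period_start, period_end, by = "day")
  starts <- rep(as.POSIXct(paste(days, "00:00:00"), tz = "UTC"), each = 4) +
    rep(c(0, 6, 12, 18) * 3600, length(days))
  win_cat <- time_category_of(starts)
  keep <- win_cat %in% categories
  starts <- starts[keep]
  win_cat <- win_cat[keep]

  day0 <- as.POSIXct(paste(period_start, "00:00:00"), tz = "UTC")
  # index each event into (window, hour-within-window, viewpoint)
  hr_abs <- floor(as.numeric(difftime(ev$timestamp, day0, units = "hours")))
  win_abs <- hr_abs %/% 6L
  hr_in <- hr_abs %% 6L
  vp_idx <- match(ev$viewpoint, vps)

  counts <- vector("list", length(starts))
  win_key <- as.numeric(difftime(starts, day0, units = "hours")) %/% 6L
  tab <- table(factor(win_abs, levels = win_key),
               factor(hr_in, levels = 0:5),
               factor(vp_idx, levels = 1:8))
  for (i in seq_along(starts)) {
    m <- matrix(tab[i, , ], nrow = 6, ncol = 8)
    dimnames(m) <- list(paste0("h", 0:5), vps)
    counts[[i]] <- m
  }
  windows <- tibble::tibble(
    window_start = starts, category = win_cat, counts = counts
  )
  windows <- windows[order(windows$window_start), , drop = FALSE]

  matrices <- lapply(stats::setNames(categories, categories), function(cat) {
    w <- windows[windows$category == cat, , drop = FALSE]
    V <- vapply(w$counts, flatten_sfp, numeric(48))
    V <- matrix(V, nrow = 48, ncol = nrow(w),
                dimnames = list(sfp_feature_names(),
                                format(w$window_start, "%Y-%m-%d %H:%M")))
    V
  })
  structure(
    list(windows = windows, matrices = matrices, n_outside = n_outside),
    class = "dws_sfp_set"
  )
}

#' @export
print.dws_sfp_set <- function(x, ...) {
  cat("<dws_sfp_set> ", nrow(x$windows), " six-hour windows (",
      paste(names(x$matrices), vapply(x$matrices, ncol, 1L),
            sep = ":", collapse = ", "),
      "), ", x$n_outside, " events outside period\n", sep = "")
  invisible(x)
}
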