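#' Build normalised daily activity matrices
#'
#' Represents each day as a 24 (hours) x 10 (sensors) matrix: hourly
#' activation counts for the nine binary channels and the hourly mean
#' wattage for the energy monitor, min-max scaled per sensor to \[0, 1\]
#' using the extremes observed over the training period. Test-day values
#' are clipped into \[0, 1\]; a sensor constant over training scales to an
#' all-zero column. Hours in which no sensor fired at all are imputed as 0
#' and flagged missing.
#'
#' @param events Event tibble (or `dws_stream` / `dws_cohort`) for one home.
#' @param period_start,period_end Days to represent (inclusive).
#' @param train_start,train_end Period defining the scaling extremes;
#'   defaults to the representation period itself.
#' @return Object of class `dws_daily_set`: `dates`, `days` (list of 24x10
#'   matrices), `missing` (list of 24-length logical flags), `scaling`
#'   (tibble `sensor`, `min`, `max`).
#' @export
build_daily_matrices <- function(events, period_start, period_end,
                                 train_start = period_start,
                                 train_end = period_end) {
  if (inherits(events, "dws_stream")) events <- events$records
  if (inherits(events, "dws_cohort")) events <- events$events
  period_start <- as.Date(period_start)
  period_end <- as.Date(period_end)
  if (period_end < period_start) stop("empty period")
  sensors <- all_viewpoints()

  raw_day <- function(date) {
    day0 <- as.POSIXct(paste(date, "00:00:00"), tz = "UTC")
    sel <- events$timestamp >= day0 & events$timestamp < day0 + 86400
    ev <- events[sel, , drop = FALSE]
    m <- matrix(0, nrow = 24, ncol = length(sensors),
                dimnames = list(NULL, sensors))
    if (nrow(ev)) {
      hr <- wallclock_hour(ev$timestamp)
      counted <- ev$viewpoint != "energy_monitor" &
        (is.na(ev$state) | ev$state == "on")
      tab <- table(factor(hr[counted], levels = 0:23),
                   factor(ev$viewpoint[counted], levels = sensors))
      m <- m + as.matrix(tab)
      en <- ev[ev$viewpoint == "energy_monitor", , drop = FALSE]
      if (nrow(en)) {
        agg <- tapply(en$value, factor(wallclock_hour(en$timestamp), levels = 0:23),
                      mean)
        agg[is.na(agg)] <- 0
        m[, "energy_monitor"] <- as.numeric(agg)
      }
    }
    m
  }

  dates <- seq(period_start, period_end, by = "day")
  days_raw <- lapply(dates, raw_day)
  train_dates <- seq(as.Date(train_start), as.Date(train_end), by = "day")
  train_raw <- if (identical(train_dates, dates)) {
    days_raw
  } else {
    lapply(train_dates, raw_day)
  }
  train_stack <- do.call(rbind, train_raw)
  lo <- apply(train_stack, 2, min)
  hi <- apply(train_stack, 2, max)
  rng <- hi - lo

  scale_day <- function(m) {
    s <- sweep(m, 2, lo)
    s <- sweep(s, 2, ifelse(rng > 0, rng, 1), "/")
    s[, rng == 0] <- 0  # zero-range rule: constant sensor scales to 0
    pmin(pmax(s, 0), 1)
  }
  days <- lapply(days_raw, scale_day)
  missing <- lapply(days_raw, function(m) rowSums(m) == 0)
  structure(
    list(dates = dates, days = days, missing = missing,
         scaling = tibble::tibble(sensor = sensors, min = lo, max = hi)),
    class = "dws_daily_set"
  )
}

# ---- isolation forest ----------------------------------------------------

# Average unsuccessful-search path length of a binary search tree of n
# points; the normalising constant of the anomaly score.
iforest_c <- function(n) {
  if (n <= 1) {
    return(0)
  }
  2 * (log(n - 1) + 0.5772156649) - 2 * (n - 1) / n
}

# Grow one isolation tree on rows of X (returned as a nested list).
grow_itree <- function(X, depth, max_depth) {
  n <- nrow(X)
  if (n <= 1 || depth >= max_depth) {
    return(list(type = "leaf", size = n))
  }
  spreads <- apply(X, 2, function(col) max(col) - min(col))
  usable <- which(spreads > 0)
  if (!length(usable)) {
    return(list(type = "leaf", size = n))
  }
  q <- usable[sample.int(length(usable), 1)]
  lo <- min(X[, q])
  hi <- max(X[, q])
  p <- runif(1, lo, hi)
  left <- X[, q] < p
  list(
    type = "split", q = q, p = p,
    left = grow_itree(X[left, , drop = FALSE], depth + 1, max_depth),
    right = grow_itree(X[!left, , drop = FALSE], depth + 1, max_depth)
  )
}

itree_path <- function(tree, x, depth = 0) {
  if (tree$type == "leaf") {
    return(depth + iforest_c(tree$size))
  }
  if (x[tree$q] < tree$p) {
    itree_path(tree$left, x, depth + 1)
  } else {
    itree_path(tree$right, x, depth + 1)
  }
}

#' Fit an isolation forest
#'
#' An ensemble of random isolation trees: each tree is grown on a random
#' subsample by recursively splitting a random feature at a random cut
#' point until points are isolated or the height limit `ceiling(log2(psi))`
#' is reached. Points that isolate quickly (short average path length) are
#' anomalous. The anomaly score is `2^(-E[h(x)] / c(psi))`, which approaches
#' 1 for anomalies and stays well below 0.5 for ordinary points.
#'
#' @param X Numeric matrix, one row per observation.
#' @param n_trees Number of trees, default 100.
#' @param sample_size Subsample per tree, default `min(256, nrow(X))`.
#' @param seed RNG seed; scores are deterministic given the seed.
#' @return Object of class `dws_iforest`.
#' @export
isolation_forest <- function(X, n_trees = 100,
                             sample_size = min(256, nrow(X)), seed = 1) {
  X <- as.matrix(X)
  max_depth <- ceiling(log2(max(2, sample_size)))
  trees <- with_local_seed(seed, {
    lapply(seq_len(n_trees), function(i) {
      idx <- sample.int(nrow(X), sample_size, replace = FALSE)
      grow_itree(X[idx, , drop = FALSE], 0, max_depth)
    })
  })
  structure(
    list(trees = trees, psi = sample_size, n_trees = n_trees, seed = seed,
         d = ncol(X)),
    class = "dws_iforest"
  )
}

#' Anomaly scores from an isolation forest
#'
#' @param forest A [isolation_forest()].
#' @param X Matrix of observations to score (rows).
#' @return Numeric scores in (0, 1); larger is more anomalous.
#' @export
iforest_score <- function(forest, X) {
  X <- as.matrix(X)
  stopifnot(ncol(X) == forest$d)
  cn <- iforest_c(forest$psi)
  apply(X, 1, function(x) {
    h <- mean(vapply(forest$trees, itree_path, numeric(1), x = x))
    2^(-h / cn)
  })
}

#' Train a per-participant day estimator and label test days
#'
#' Flattens each daily activity matrix to a 240-dimensional vector, fits an
#' isolation forest on the training days (at least 30, the length of the
#' personalisation window) and labels each test day normal/abnormal by
#' thresholding the anomaly score (default 0.5, the score's natural
#' midpoint).
#'
#' @param train_days,test_days `dws_daily_set` objects (or lists of 24xN
#'   matrices).
#' @param n_trees,sample_size,threshold Isolation-forest parameters.
#' @param seed RNG seed.
#' @param allow_short Permit fewer than 30 training days.
#' @return List of class `dws_day_labels`: `labels` (tibble `date`, `score`,
#'   `label`), `threshold`, `forest`.
#' @export
fit_and_label <- function(train_days, test_days, n_trees = 100,
                          sample_size = NULL, threshold = 0.5, seed = 1,
                          allow_short = FALSE) {
  tr <- daily_feature_matrix(train_days)
  te <- daily_feature_matrix(test_days)
  if (nrow(tr$X) < 30 && !allow_short) {
    stop("need at least 30 training days (use allow_short to override)")
  }
  sample_size <- sample_size %||% min(256, nrow(tr$X))
  forest <- isolation_forest(tr$X, n_trees = n_trees,
                             sample_size = sample_size, seed = seed)
  score <- iforest_score(forest, te$X)
  labels <- tibble::tibble(
    date = te$dates,
    score = as.numeric(score),
    label = ifelse(score > threshold, "abnormal", "normal")
  )
  structure(list(labels = labels, threshold = threshold, forest = forest),
            class = "dws_day_labels")
}

daily_feature_matrix <- function(days) {
  if (inherits(days, "dws_daily_set")) {
    X <- t(vapply(days$days, as.vector, numeric(24 * 10)))
    list(X = X, dates = days$dates)
  } else {
    X <- t(vapply(days, as.vector, numeric(length(as.vector(days[[1]])))))
    list(X = X, dates = seq_along(days))
  }
}
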