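#' MAD deviation scores of cluster sizes
#'
#' For an array of cluster member counts, scores each cluster by its absolute
#' deviation from the median count, normalised by the median absolute
#' deviation with consistency constant `b = 1.4826` (which makes the MAD a
#' consistent estimator of the standard deviation under normality):
#' `score_i = |count_i - median| / (b * median_j |count_j - median|)`.
#' When the MAD denominator is zero (no dispersion) all scores are zero.
#'
#' @param counts Positive integer vector of cluster sizes.
#' @param b Consistency constant, default 1.4826.
#' @return Non-negative numeric scores, one per cluster.
#' @export
mad_deviation_scores <- function(counts, b = 1.4826) {
  if (!length(counts)) stop("counts must be non-empty")
  if (any(counts < 1)) stop("cluster sizes must be >= 1")
  med <- median(counts)
  dev <- abs(counts - med)
  denom <- b * median(dev)
  if (denom == 0) {
    return(rep(0, length(counts)))
  }
  dev / denom
}

#' Categorise clusters by repeatability
#'
#' Assigns each cluster one of three repeatability categories from its MAD
#' deviation score using the rejection thresholds `d_low` and `d_high`:
#' scores below `d_low` are highly repetitive patterns (HSFP), scores from
#' `d_low` up to (but excluding) `d_high` are low-repetitive (LSFP), and
#' scores at or above `d_high` are rarely repetitive (RSFP) — the anomaly
#' category. A score exactly at `d_low` is assigned LSFP (the conservative
#' choice: fewer windows are declared fully routine).
#'
#' With `one_sided = TRUE` only clusters *smaller* than the median can be
#' RSFP (rare = small); the default follows the unsigned score, under which
#' an unusually large cluster is also flagged.
#'
#' @param scores MAD deviation scores, as from [mad_deviation_scores()].
#' @param d_low,d_high Rejection thresholds, defaults 1 and 2.5.
#' @param counts Cluster sizes (required for `one_sided`).
#' @param one_sided Restrict RSFP to below-median clusters (default FALSE).
#' @return Character vector in `{"HSFP","LSFP","RSFP"}`, one per cluster.
#' @export
categorise_clusters <- function(scores, d_low = 1, d_high = 2.5,
                                counts = NULL, one_sided = FALSE) {
  if (d_low >= d_high) stop("d_low must be < d_high")
  cat <- ifelse(scores < d_low, "HSFP", ifelse(scores < d_high, "LSFP", "RSFP"))
  if (one_sided) {
    if (is.null(counts)) stop("one_sided categorisation needs cluster counts")
    big <- counts > median(counts)
    cat[cat == "RSFP" & big] <- "LSFP"
  }
  cat
}

#' Build an activity profile from a profiling period
#'
#' Runs the full decomposition-based profiling chain for each requested time
#' category: build the 48 x n six-hour SFP matrix, fit the NMF (with rank
#' selection unless `rank` is given), cluster the windows in feature space,
#' and categorise the clusters as HSFP/LSFP/RSFP by MAD score of their
#' sizes.
#'
#' @param events Event tibble, `dws_stream` or `dws_cohort` for one home.
#' @param period_start,period_end Profiling period (dates, inclusive);
#'   typically around three months.
#' @param categories Time categories to profile, default all four.
#' @param rank Fixed NMF rank, or `NULL` to select via [select_rank()].
#' @param r_range Candidate ranks when selecting, default `1:6`.
#' @param k_range Candidate cluster counts, default `2:10`.
#' @param d_low,d_high MAD rejection thresholds (1 and 2.5).
#' @param one_sided Passed to [categorise_clusters()].
#' @param seed RNG seed shared by the NMF restarts and k-means.
#' @param ... Further arguments to [acls_nmf()].
#' @return Object of class `dws_profile`: per category a list with `model`
#'   (`dws_nmf`), `clusters` (`dws_clusters`), `counts`, `scores`,
#'   `categories` (per-cluster labels) and `window_start`s; plus the
#'   thresholds and seed.
#' @export
build_activity_profile <- function(events, period_start, period_end,
                                   categories = time_categories(),
                                   rank = NULL, r_range = 1:6,
                                   k_range = 2:10,
                                   d_low = 1, d_high = 2.5,
                                   one_sided = FALSE, seed = 1, ...) {
  sfp <- build_sfp_windows(events, period_start, period_end, categories)
  per_cat <- lapply(stats::setNames(categories, categories), function(cat) {
    V <- sfp$matrices[[cat]]
    r <- rank %||% select_rank(V, r_range, seed = seed, ...)$rank
    model <- acls_nmf(V, r, seed = seed, ...)
    clusters <- cluster_feature_space(model, k_range, seed = seed)
    counts <- tabulate(clusters$labels, clusters$k)
    scores <- mad_deviation_scores(counts)
    cats <- categorise_clusters(scores, d_low, d_high,
                                counts = counts, one_sided = one_sided)
    list(
      model = model, clusters = clusters, counts = counts, scores = scores,
      categories = cats,
      window_start = sfp$windows$window_start[sfp$windows$category == cat]
    )
  })
  structure(
    list(per_category = per_cat, d_low = d_low, d_high = d_high,
         one_sided = one_sided, seed = seed),
    class = "dws_profile"
  )
}

#' @export
print.dws_profile <- function(x, ...) {
  cat("<dws_profile> rejection thresholds ", x$d_low, "/", x$d_high, "\n",
      sep = "")
  for (cat_name in names(x$per_category)) {
    pc <- x$per_category[[cat_name]]
    cat(sprintf(
      "  %-9s r=%d k=%d sizes=%s categories=%s\n", cat_name, pc$model$r,
      pc$clusters$k, paste(pc$counts, collapse = "/"),
      paste(pc$categories, collapse = "/")
    ))
  }
  invisible(x)
}

#' Classify a new six-hour window against a profile
#'
#' Projects the flattened window onto the profile's feature matrix `W` by
#' non-negative least squares, normalises the coordinates consistently with
#' training, assigns the window to the nearest cluster centroid (Euclidean)
#' and inherits that cluster's HSFP/LSFP/RSFP category.
#'
#' @param counts A 6x8 count matrix or flattened 48-vector.
#' @param profile A [build_activity_profile()] result.
#' @param category The window's time category.
#' @return List: `category` (HSFP/LSFP/RSFP), `cluster` (nearest cluster id),
#'   `coords` (non-negative feature-space coordinates before normalisation).
#' @export
classify_window <- function(counts, profile, category) {
  pc <- profile$per_category[[category]]
  if (is.null(pc)) stop("no profile for time category '", category, "'")
  v <- if (is.matrix(counts)) flatten_sfp(counts) else counts
  stopifnot(length(v) == 48)
  h <- pracma::lsqnonneg(pc$model$W, as.numeric(v))$x
  coords <- h
  if (pc$clusters$normalise) {
    s <- sum(abs(h))
    if (s > 0) h <- h / s
  }
  d2 <- colSums((t(pc$clusters$centroids) - h)^2)
  cl <- which.min(d2)
  list(category = pc$categories[cl], cluster = as.integer(cl), coords = coords)
}
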