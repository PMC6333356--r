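# Mean silhouette width of a labelled point set (rows = points). Computed
# directly from the pairwise distance matrix; returns NA when any cluster is
# a singleton-only configuration that leaves silhouette undefined (k == 1).
mean_silhouette <- function(X, labels) {
  k <- length(unique(labels))
  n <- nrow(X)
  if (k < 2 || n < 3) {
    return(NA_real_)
  }
  D <- as.matrix(dist(X))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    n_own <- sum(own) - 1L
    if (n_own == 0L) {
      s[i] <- 0  # singleton convention
      next
    }
    a <- sum(D[i, own]) / n_own
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(l) {
      mean(D[i, labels == l])
    }, numeric(1)))
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  mean(s)
}

# L1-normalise columns; all-zero columns are left untouched.
l1_normalise_cols <- function(M) {
  cs <- colSums(abs(M))
  cs[cs == 0] <- 1
  sweep(M, 2, cs, "/")
}

#' Cluster six-hour windows in the NMF feature space
#'
#' Each window's column of `H` gives its coordinates in the r-dimensional
#' feature space. Columns are L1-normalised (so clusters reflect pattern
#' shape, not overall activity level) and partitioned by k-means with 10
#' restarts; the number of clusters is chosen to maximise the mean
#' silhouette over `k_range`. The feature rank r and the cluster count k are
#' independent. When all coordinates coincide the assignment degenerates to
#' a single cluster with an undefined silhouette.
#'
#' @param model A fitted [acls_nmf()] model (or a bare coefficient matrix H).
#' @param k_range Candidate cluster counts, default `2:10` (capped at n - 1).
#' @param seed RNG seed for the k-means restarts.
#' @param normalise Apply L1 column normalisation before clustering
#'   (default TRUE).
#' @return Object of class `dws_clusters`: `k`, `labels` (per window),
#'   `centroids` (k x r), `silhouette`, `degenerate`, `normalise`.
#' @export
cluster_feature_space <- function(model, k_range = 2:10, seed = 1,
                                  normalise = TRUE) {
  H <- if (inherits(model, "dws_nmf")) model$H else as.matrix(model)
  n <- ncol(H)
  if (n < 3) stop("need at least 3 windows to cluster")
  coords <- if (normalise) l1_normalise_cols(H) else H
  X <- t(coords)
  if (max(dist(X)) < 1e-12) {
    return(structure(
      list(k = 1L, labels = rep(1L, n), centroids = X[1, , drop = FALSE],
           silhouette = NA_real_, degenerate = TRUE, normalise = normalise),
      class = "dws_clusters"
    ))
  }
  k_range <- k_range[k_range >= 2 & k_range <= n - 1]
  k_range <- k_range[k_range <= nrow(unique(X))]
  if (!length(k_range)) k_range <- 2L
  best <- NULL
  with_local_seed(seed, {
    for (k in k_range) {
      km <- suppressWarnings(kmeans(X, centers = k, nstart = 10, iter.max = 50))
      sil <- mean_silhouette(X, km$cluster)
      if (is.null(best) || (!is.na(sil) && sil > best$sil)) {
        best <- list(km = km, sil = sil, k = k)
      }
    }
  })
  structure(
    list(
      k = as.integer(best$k),
      labels = as.integer(best$km$cluster),
      centroids = best$km$centers,
      silhouette = best$sil,
      degenerate = FALSE,
      normalise = normalise
    ),
    class = "dws_clusters"
  )
}

#' @export
print.dws_clusters <- function(x, ...) {
  cat("<dws_clusters> k = ", x$k,
      ", sizes: ", paste(tabulate(x$labels, x$k), collapse = "/"),
      ", mean silhouette ", signif(x$silhouette, 3),
      if (x$degenerate) " [degenerate]", "\n", sep = "")
  invisible(x)
}
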