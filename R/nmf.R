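#' Non-negative matrix factorisation by alternating constrained least squares
#'
#' Factorises a non-negative matrix `V` (m x n) as `W %*% H` with `W` (m x r)
#' and `H` (r x n) entrywise non-negative, minimising the squared Frobenius
#' error. Each alternating step solves a ridge-regularised least-squares
#' problem for one block with the other fixed and clips negative entries to
#' zero (the "constrained" step). Because of the clipping the raw update is
#' not guaranteed monotone, so the iteration tracks the objective and stops
#' (keeping the previous iterate) if it would increase beyond tolerance: the
#' reported objective trajectory is therefore non-increasing. Of `n_init`
#' random restarts the factorisation with the smallest residual is returned.
#'
#' @param V Non-negative numeric matrix.
#' @param r Rank, `1 <= r < min(dim(V))`.
#' @param max_iter Maximum alternating iterations per restart.
#' @param tol Relative objective-change stopping tolerance.
#' @param n_init Number of random restarts (default 10).
#' @param lambda Ridge regularisation added to each block solve.
#' @param seed RNG seed controlling the restarts.
#' @return Object of class `dws_nmf`: `W`, `H`, `r`, `residual`
#'   (`||V - WH||_F`), `objective` (non-increasing per-iteration trajectory
#'   of the winning restart), `converged`, `n_init`, `seed`.
#' @export
acls_nmf <- function(V, r, max_iter = 500, tol = 1e-6, n_init = 10,
                     lambda = 1e-3, seed = 1) {
  V <- as.matrix(V)
  if (any(V < 0)) stop("V must be entrywise non-negative")
  m <- nrow(V)
  n <- ncol(V)
  if (r < 1 || r >= min(m, n)) stop("rank r must satisfy 1 <= r < min(dim(V))")
  best <- NULL
  with_local_seed(seed, {
    for (init in seq_len(n_init)) {
      fit <- acls_single(V, r, max_iter, tol, lambda)
      if (is.null(best) || fit$residual < best$residual) best <- fit
    }
  })
  # fix the scale indeterminacy of the factorisation: W columns sum to 1,
  # H rows absorb the scale, so H coordinates are comparable across factors
  csum <- colSums(best$W)
  pos <- csum > 0
  best$W[, pos] <- sweep(best$W[, pos, drop = FALSE], 2, csum[pos], "/")
  best$H[pos, ] <- sweep(best$H[pos, , drop = FALSE], 1, csum[pos], "*")
  structure(
    c(best, list(r = as.integer(r), n_init = as.integer(n_init),
                 seed = as.integer(seed))),
    class = "dws_nmf"
  )
}

acls_single <- function(V, r, max_iter, tol, lambda) {
  m <- nrow(V)
  n <- ncol(V)
  scale <- mean(V[V > 0]) %||% 1
  if (!is.finite(scale) || scale <= 0) scale <- 1
  W <- matrix(runif(m * r, 0, sqrt(scale)), m, r)
  H <- matrix(runif(r * n, 0, sqrt(scale)), r, n)
  ridge <- diag(lambda, r)
  best_obj <- sum((V - W %*% H)^2)
  best_W <- W
  best_H <- H
  trace <- best_obj
  stall <- 0L
  converged <- FALSE
  # the clipped alternating step is not monotone, so iterate through
  # temporary increases, keep the best iterate seen, and stop once no
  # improvement has been accepted for a while
  for (it in seq_len(max_iter)) {
    H <- solve(crossprod(W) + ridge, crossprod(W, V))
    H[H < 0] <- 0
    W <- t(solve(tcrossprod(H) + ridge, tcrossprod(H, V)))
    W[W < 0] <- 0
    obj <- sum((V - W %*% H)^2)
    if (obj < best_obj - tol * max(best_obj, .Machine$double.eps)) {
      best_obj <- obj
      best_W <- W
      best_H <- H
      trace <- c(trace, obj)
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= 10L) {
        converged <- TRUE
        break
      }
    }
  }
  list(W = best_W, H = best_H, residual = sqrt(best_obj), objective = trace,
       converged = converged)
}

#' @export
print.dws_nmf <- function(x, ...) {
  cat("<dws_nmf> rank ", x$r, " (", nrow(x$W), " x ", ncol(x$H),
      "), residual ", signif(x$residual, 4),
      if (!x$converged) " [not converged]", "\n", sep = "")
  invisible(x)
}

#' Select the NMF rank from the residual curve
#'
#' Fits [acls_nmf()] for every rank in `r_range` and reports the
#' root-mean-square residual per rank. The selected rank is the elbow of the
#' curve: the last rank before the relative residual improvement first drops
#' below `improve_frac`. A rank whose RMS residual is already numerically
#' zero is selected immediately.
#'
#' @param V Non-negative data matrix.
#' @param r_range Candidate ranks, default `1:6`.
#' @param improve_frac Elbow threshold on relative improvement (default 0.05).
#' @param ... Passed to [acls_nmf()].
#' @return List: `rank` (selected), `curve` (tibble `r`, `rms_residual`).
#' @export
select_rank <- function(V, r_range = 1:6, improve_frac = 0.05, ...) {
  if (!length(r_range)) stop("r_range must be non-empty")
  r_range <- sort(unique(as.integer(r_range)))
  r_range <- r_range[r_range >= 1 & r_range < min(dim(V))]
  if (!length(r_range)) stop("no admissible ranks for this matrix")
  mn <- prod(dim(V))
  rms <- vapply(r_range, function(r) {
    acls_nmf(V, r, ...)$residual / sqrt(mn)
  }, numeric(1))
  curve <- tibble::tibble(r = r_range, rms_residual = rms)
  sel <- r_range[length(r_range)]
  for (i in seq_along(r_range)) {
    if (rms[i] < 1e-9) {
      sel <- r_range[i]
      break
    }
    if (i > 1) {
      improvement <- (rms[i - 1] - rms[i]) / max(rms[i - 1], .Machine$double.eps)
      if (improvement < improve_frac) {
        sel <- r_range[i - 1]
        break
      }
    }
  }
  list(rank = sel, curve = curve)
}
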