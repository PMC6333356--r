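# Independent oracles used to cross-check package implementations. These are
# deliberately written as straight-line re-implementations from first
# principles, sharing no code with R/.

# Lee-Seung multiplicative-update NMF, run to convergence. Used as the
# reference optimiser for the alternating-least-squares solver.
mu_nmf <- function(V, r, max_iter = 3000, tol = 1e-10) {
  m <- nrow(V)
  n <- ncol(V)
  W <- matrix(runif(m * r, 0.1, 1), m, r)
  H <- matrix(runif(r * n, 0.1, 1), r, n)
  eps <- 1e-12
  obj <- sum((V - W %*% H)^2)
  for (it in seq_len(max_iter)) {
    H <- H * (t(W) %*% V) / (t(W) %*% W %*% H + eps)
    W <- W * (V %*% t(H)) / (W %*% H %*% t(H) + eps)
    obj_new <- sum((V - W %*% H)^2)
    if (abs(obj - obj_new) < tol * max(1, obj)) break
    obj <- obj_new
  }
  list(W = W, H = H, objective = obj_new, residual = sqrt(obj_new))
}

# Direct, loop-based restatement of the deviation-score + three-way
# categorisation rule, independent of the vectorised package code.
mad_categorise_oracle <- function(counts, b = 1.4826, d_low = 1, d_high = 2.5) {
  med <- sort(counts)[ceiling(length(counts) / 2)]
  if (length(counts) %% 2 == 0) {
    s <- sort(counts)
    med <- (s[length(counts) / 2] + s[length(counts) / 2 + 1]) / 2
  }
  devs <- numeric(length(counts))
  for (i in seq_along(counts)) devs[i] <- abs(counts[i] - med)
  sdev <- sort(devs)
  mad_raw <- if (length(devs) %% 2 == 1) {
    sdev[(length(devs) + 1) / 2]
  } else {
    (sdev[length(devs) / 2] + sdev[length(devs) / 2 + 1]) / 2
  }
  out <- character(length(counts))
  for (i in seq_along(counts)) {
    score <- if (mad_raw == 0) 0 else devs[i] / (b * mad_raw)
    out[i] <- if (score < d_low) {
      "HSFP"
    } else if (score < d_high) {
      "LSFP"
    } else {
      "RSFP"
    }
  }
  out
}

# Independent banded-score lookup written as an explicit band table.
dhs_band_oracle <- function(parameter, value) {
  bands <- list(
    systolic_bp = data.frame(
      lo = c(-Inf, 91, 101, 111, 220),
      hi = c(90, 100, 110, 219, Inf),
      score = c(3, 2, 1, 0, 3)
    ),
    pulse = data.frame(
      lo = c(-Inf, 41, 51, 91, 111, 131),
      hi = c(40, 50, 90, 110, 130, Inf),
      score = c(3, 1, 0, 1, 2, 3)
    ),
    body_temperature = data.frame(
      lo = c(-Inf, 35.1, 36.1, 38.1, 39.1),
      hi = c(35, 36, 38, 39, Inf),
      score = c(3, 1, 0, 1, 2)
    ),
    spo2 = data.frame(
      lo = c(-Inf, 92, 94, 96),
      hi = c(91, 93, 95, Inf),
      score = c(3, 2, 1, 0)
    )
  )
  digits <- if (parameter == "body_temperature") 1 else 0
  p <- 10^digits
  v <- sign(value) * floor(abs(value) * p + 0.5) / p
  b <- bands[[parameter]]
  hit <- which(v >= b$lo & v <= b$hi)
  stopifnot(length(hit) == 1)
  b$score[hit]
}
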