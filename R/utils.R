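# Internal helpers shared across modules.

# Half-up rounding to `digits` decimals (printed-report convention; base
# round() rounds half to even).
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  # the epsilon guards against decimal literals sitting just under .5
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# All timestamps are naive local wall-clock time carried as UTC POSIXct so
# that hourly bins are clock-aligned and unaffected by DST rules.
as_wallclock <- function(x) {
  if (inherits(x, "POSIXct")) {
    attr(x, "tzone") <- "UTC"
    return(x)
  }
  as.POSIXct(x, tz = "UTC")
}

wallclock_hour <- function(ts) {
  as.integer(format(ts, "%H", tz = "UTC"))
}

wallclock_date <- function(ts) {
  as.Date(format(ts, "%Y-%m-%d", tz = "UTC"))
}

frobenius <- function(M) sqrt(sum(M^2))

# Run `expr` under a locally-seeded RNG, restoring the caller's RNG state.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
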