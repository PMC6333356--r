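# Small fixtures built in code at test time.

# Quiet simulation config: nuisance processes off so that counts are pure
# Poisson draws from the configured rate profiles.
quiet_config <- function(n_days, seed, ...) {
  simulation_config(
    n_homes = 1, n_days = n_days, seed = seed,
    nuisance = list(guest_prob = 0, pet_rate = 0, missing_prob = 0,
                    restless_prob = 0, upset_day_prob = 0),
    ...
  )
}

events_tbl <- function(times, viewpoint, state = "on", home_id = "H001") {
  tibble::tibble(
    home_id = home_id,
    timestamp = as.POSIXct(times, tz = "UTC"),
    viewpoint = viewpoint,
    state = state,
    value = NA_real_
  )
}

vitals_tbl <- function(times, parameter, value, home_id = "H001") {
  tibble::tibble(
    home_id = home_id,
    timestamp = as.POSIXct(times, tz = "UTC"),
    parameter = parameter,
    value = value
  )
}

# Bed-pressure on/off events for given occupancy epochs plus ambient events.
night_events <- function(epochs, ambient = NULL, home_id = "H001") {
  bed <- dplyr::bind_rows(lapply(epochs, function(ep) {
    tibble::tibble(
      home_id = home_id,
      timestamp = as.POSIXct(c(ep[1], ep[2]), tz = "UTC"),
      viewpoint = "bed_pressure",
      state = c("on", "off"),
      value = NA_real_
    )
  }))
  out <- if (is.null(ambient)) bed else dplyr::bind_rows(bed, ambient)
  dplyr::arrange(out, timestamp)
}

# A hand-built activity profile with two known patterns: a "routine" pattern
# concentrated on the bed-pressure channel and a "wandering" pattern spread
# over hallway/kitchen/living room. Cluster 1 is HSFP, cluster 2 RSFP.
toy_profile <- function(category = "night") {
  vps <- sfp_viewpoints()
  routine <- matrix(0, 6, 8, dimnames = list(NULL, vps))
  routine[, "bed_pressure"] <- 1
  wander <- matrix(0, 6, 8, dimnames = list(NULL, vps))
  wander[, c("hallway_pir", "kitchen_motion", "living_room_pir")] <- 1
  W <- cbind(flatten_sfp(routine), flatten_sfp(wander))
  W <- sweep(W, 2, colSums(W), "/")
  centroids <- rbind(c(1, 0), c(0, 1))
  clusters <- structure(
    list(k = 2L, labels = c(1L, 1L, 1L, 2L), centroids = centroids,
         silhouette = 0.9, degenerate = FALSE, normalise = TRUE),
    class = "dws_clusters"
  )
  model <- structure(
    list(W = W, H = NULL, r = 2L, residual = 0, objective = 0,
         converged = TRUE, n_init = 1L, seed = 1L),
    class = "dws_nmf"
  )
  per <- list(list(
    model = model, clusters = clusters, counts = c(30L, 3L),
    scores = c(0, 10), categories = c("HSFP", "RSFP"),
    window_start = as.POSIXct(character(), tz = "UTC")
  ))
  names(per) <- category
  structure(
    list(per_category = per, d_low = 1, d_high = 2.5, one_sided = FALSE,
         seed = 1),
    class = "dws_profile"
  )
}

# 6x8 count window dominated by the given viewpoints.
toy_window <- function(active, level = 5) {
  vps <- sfp_viewpoints()
  m <- matrix(0, 6, 8, dimnames = list(NULL, vps))
  m[, active] <- level
  m
}
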