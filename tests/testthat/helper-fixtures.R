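# Small programmatic fixtures shared across test files.

# A fix stream at regular cadence visiting a sequence of (lat, lon) points.
make_fixes <- function(lat, lon, start = "2023-01-04 08:00:00",
                       step_s = 600, participant_id = "P1") {
  n <- length(lat)
  tibble::tibble(
    participant_id = participant_id,
    timestamp = as.POSIXct(start, tz = "UTC") + (seq_len(n) - 1) * step_s,
    lat = lat,
    lon = lon
  )
}

# Displace a point by metres east/north on the same 6371.0088 km sphere
# the distance functions use (flat-earth update, fine at city scale).
move_m <- function(lat, lon, east_m = 0, north_m = 0) {
  m_per_deg <- 2 * pi * 6371008.8 / 360
  list(
    lat = lat + north_m / m_per_deg,
    lon = lon + east_m / (m_per_deg * cos(lat * pi / 180))
  )
}

# A minimal weekly table (already aggregated) for decomposition tests.
make_weekly <- function(values_by_participant, week0 = as.Date("2023-01-04")) {
  purrr::imap(values_by_participant, function(v, id) {
    tibble::tibble(
      participant_id = id,
      week_index = seq_along(v) - 1L,
      week_start = week0 + 7 * (seq_along(v) - 1L),
      mean_homestay = v,
      mean_entropy = v / 10,
      mean_distance = v * 2,
      n_gps_days = 7L
    )
  }) |>
    dplyr::bind_rows()
}

# The full Table-style model formula used throughout.
event_formula <- outcome_event ~ hw_within + en_within + di_within +
  hw_between + en_between + di_between + weeks_since_baseline

# Seeded latent features + outcome generation (simulate_outcomes itself is
# deliberately unseeded; the seeding wrappers live in simulate_panel/_cohort).
with_seed_outcomes <- function(cfg) {
  set.seed(cfg$seed)
  latent <- gpsrisk:::latent_weekly_features(cfg)
  simulate_outcomes(cfg, latent)
}
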