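# Daily mobility features from raw GPS fix streams: dwell assignment,
# greedy location clustering, night-window home inference, and the three
# daily summaries (homestay, location entropy, distance traveled).

EARTH_RADIUS_KM <- 6371.0088

#' Great-circle distance between coordinate pairs
#'
#' Haversine distance on a sphere of radius 6371.0088 km. Vectorised over
#' all four arguments with the usual recycling rules.
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in decimal degrees.
#' @return Distance(s) in kilometres.
#' @examples
#' haversine_km(0, 0, 0, 1) # one degree of longitude on the equator
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2) {
  check_latlon(lat1, lon1)
  check_latlon(lat2, lon2)
  rad <- pi / 180
  dlat <- (lat2 - lat1) * rad
  dlon <- (lon2 - lon1) * rad
  a <- sin(dlat / 2)^2 + cos(lat1 * rad) * cos(lat2 * rad) * sin(dlon / 2)^2
  2 * EARTH_RADIUS_KM * asin(pmin(1, sqrt(a)))
}

check_latlon <- function(lat, lon) {
  if (any(!is.finite(lat)) || any(!is.finite(lon))) {
    stop("latitude/longitude must be finite", call. = FALSE)
  }
  if (any(lat < -90 | lat > 90)) stop("latitude outside [-90, 90]", call. = FALSE)
  if (any(lon < -180 | lon > 180)) stop("longitude outside [-180, 180]", call. = FALSE)
  invisible(TRUE)
}

#' Assign per-fix dwell times
#'
#' Each fix's dwell is the time to the next fix by the same participant,
#' capped at `gap_cap_min` minutes so unobserved gaps do not inflate any
#' location's time; the last fix of each local day dwells until local
#' midnight (same cap).
#'
#' @param fixes Tibble with `participant_id`, `timestamp` (POSIXct), `lat`,
#'   `lon` columns, strictly time-ordered within participant.
#' @param gap_cap_min Dwell cap in minutes (default 30).
#' @return The input with `dwell_s` and `date` columns added.
#' @export
assign_dwell <- function(fixes, gap_cap_min = 30) {
  stopifnot(is.data.frame(fixes))
  if (nrow(fixes) == 0) {
    return(dplyr::mutate(tibble::as_tibble(fixes),
      date = as.Date(character()), dwell_s = numeric()
    ))
  }
  cap_s <- gap_cap_min * 60
  fixes <- tibble::as_tibble(fixes)
  bad <- fixes |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::mutate(.dt = c(diff(as.numeric(.data$timestamp)), Inf)) |>
    dplyr::ungroup()
  if (any(bad$.dt <= 0)) {
    i <- which(bad$.dt <= 0)[1]
    stop(sprintf(
      "timestamps not strictly increasing for participant %s at row %d",
      bad$participant_id[i], i
    ), call. = FALSE)
  }
  fixes |>
    dplyr::mutate(date = as.Date(.data$timestamp, tz = lubridate::tz(.data$timestamp))) |>
    dplyr::group_by(.data$participant_id, .data$date) |>
    dplyr::mutate(
      .to_next = c(diff(as.numeric(.data$timestamp)), NA_real_),
      .to_midnight = as.numeric(lubridate::ceiling_date(
        .data$timestamp[dplyr::n()], "day"
      )) - as.numeric(.data$timestamp[dplyr::n()]),
      dwell_s = pmin(dplyr::coalesce(.data$.to_next, .data$.to_midnight), cap_s)
    ) |>
    dplyr::ungroup() |>
    dplyr::select(-".to_next", -".to_midnight")
}

#' Greedy sequential location clustering
#'
#' Processes fixes in time order; a fix joins the nearest existing cluster
#' whose centroid lies within `radius_m`, otherwise opens a new cluster.
#' Centroids are dwell-weighted running means, so the procedure is
#' deterministic given input order.
#'
#' @param fixes Tibble for one participant with `lat`, `lon`, `dwell_s`.
#' @param radius_m Cluster radius in metres (default 200).
#' @return List with `clusters` (tibble: `cluster_id`, `centroid_lat`,
#'   `centroid_lon`, `total_dwell_s`) and `assignment` (integer vector,
#'   one entry per fix).
#' @export
cluster_locations <- function(fixes, radius_m = 200) {
  n <- nrow(fixes)
  empty <- tibble::tibble(
    cluster_id = integer(), centroid_lat = numeric(),
    centroid_lon = numeric(), total_dwell_s = numeric()
  )
  if (n == 0) return(list(clusters = empty, assignment = integer()))
  res <- cluster_greedy_cpp(
    fixes$lat, fixes$lon,
    if ("dwell_s" %in% names(fixes)) fixes$dwell_s else rep(1, n),
    radius_m / 1000, EARTH_RADIUS_KM
  )
  list(
    clusters = tibble::tibble(
      cluster_id = seq_along(res$lat),
      centroid_lat = res$lat, centroid_lon = res$lon,
      total_dwell_s = res$dwell
    ),
    assignment = res$assignment
  )
}

#' Infer the home location from night-time dwell
#'
#' Home is the centroid of the location cluster accumulating the most
#' dwell inside the night window (02:00-06:00 local) over the whole study
#' period. Ties are broken by larger all-day dwell, then by earlier first
#' visit.
#'
#' @param fixes One participant's fixes with `timestamp` and `dwell_s`.
#' @param radius_m Cluster radius in metres.
#' @param night_start,night_end Night window bounds as hours of the local
#'   day (defaults 2 and 6).
#' @return Tibble row: `lat`, `lon`, `night_dwell_s`.
#' @export
estimate_home <- function(fixes, radius_m = 200, night_start = 2, night_end = 6) {
  hr <- lubridate::hour(fixes$timestamp) + lubridate::minute(fixes$timestamp) / 60
  night <- hr >= night_start & hr < night_end
  if (!any(night)) {
    stop("home unidentifiable: no fixes in the night window", call. = FALSE)
  }
  cl <- cluster_locations(fixes, radius_m)
  night_dwell <- tapply(fixes$dwell_s[night], cl$assignment[night], sum)
  all_dwell <- cl$clusters$total_dwell_s
  first_visit <- tapply(seq_len(nrow(fixes)), cl$assignment, min)
  cand <- as.integer(names(night_dwell))
  score <- order(
    -night_dwell,
    -all_dwell[cand],
    first_visit[as.character(cand)]
  )
  best <- cand[score[1]]
  tibble::tibble(
    lat = cl$clusters$centroid_lat[best],
    lon = cl$clusters$centroid_lon[best],
    night_dwell_s = unname(night_dwell[as.character(best)])
  )
}

#' Daily homestay in hours
#'
#' Sum of dwell over fixes within `radius_m` of the home coordinate,
#' in hours.
#'
#' @param fixes One day of fixes with `lat`, `lon`, `dwell_s`.
#' @param home_lat,home_lon Home coordinate.
#' @param radius_m Homestay radius in metres (default 200).
#' @export
daily_homestay <- function(fixes, home_lat, home_lon, radius_m = 200) {
  if (nrow(fixes) == 0) return(0)
  at_home <- haversine_km(fixes$lat, fixes$lon, home_lat, home_lon) <= radius_m / 1000
  sum(fixes$dwell_s[at_home]) / 3600
}

#' Shannon entropy of daily dwell over location clusters
#'
#' H = -sum p_i log p_i in nats, where p_i is the fraction of the day's
#' observed dwell spent in cluster i. Zero-dwell clusters contribute 0.
#'
#' @param dwell_by_cluster Numeric vector of per-cluster dwell (seconds).
#' @return Entropy in nats, or `NA` when total dwell is zero.
#' @export
daily_entropy <- function(dwell_by_cluster) {
  tot <- sum(dwell_by_cluster)
  if (!is.finite(tot) || tot <= 0) return(NA_real_)
  p <- dwell_by_cluster / tot
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Total daily distance traveled
#'
#' Sum of haversine distances between consecutive same-day fixes, after
#' discarding (a) segments faster than `max_speed_kmh` (GPS teleports) and
#' (b) segments shorter than `min_segment_km` (stationary jitter). Either
#' filter can be disabled with `Inf` / `0`.
#'
#' @param fixes One day of time-ordered fixes with `timestamp`, `lat`, `lon`.
#' @param max_speed_kmh Speed filter; segments above it are skipped
#'   (default `Inf`, i.e. off).
#' @param min_segment_km Jitter filter; segments below it are skipped
#'   (default 0, i.e. off).
#' @return Distance in km; 0 for fewer than two fixes.
#' @export
daily_distance <- function(fixes, max_speed_kmh = Inf, min_segment_km = 0) {
  n <- nrow(fixes)
  if (n <= 1) return(0)
  d <- haversine_km(
    fixes$lat[-n], fixes$lon[-n],
    fixes$lat[-1], fixes$lon[-1]
  )
  dt_h <- diff(as.numeric(fixes$timestamp)) / 3600
  speed <- ifelse(dt_h > 0, d / dt_h, Inf)
  sum(d[speed <= max_speed_kmh & d >= min_segment_km])
}

#' Daily mobility features for a whole cohort
#'
#' Runs the full per-participant pipeline: dwell assignment, location
#' clustering, night-window home inference, then per-day homestay (h),
#' entropy (nats), and distance (km). Participants with no night-window
#' fixes cannot have a home inferred and are dropped with a warning, as
#' studies drop participants without usable geolocation.
#'
#' @param gps Tibble of fixes: `participant_id`, `timestamp`, `lat`, `lon`,
#'   optionally `accuracy_m`.
#' @param radius_m Cluster/homestay radius in metres (default 200).
#' @param gap_cap_min Dwell cap in minutes (default 30).
#' @param max_speed_kmh,min_segment_km Distance filters, see
#'   [daily_distance()]. Defaults: 300 km/h speed filter, 0.15 km jitter
#'   filter.
#' @return Tibble: `participant_id`, `date`, `homestay_h`, `entropy_nats`,
#'   `distance_km`, `n_fixes`, `observed_span_h`.
#' @examples
#' cohort <- simulate_cohort(sim_config(n_participants = 2, n_weeks = 2, seed = 1))
#' daily_features(cohort$gps)
#' @export
daily_features <- function(gps, radius_m = 200, gap_cap_min = 30,
                           max_speed_kmh = 300, min_segment_km = 0.15) {
  gps <- assign_dwell(gps, gap_cap_min)
  out <- gps |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::group_map(function(df, key) {
      home <- tryCatch(estimate_home(df, radius_m), error = function(e) NULL)
      if (is.null(home)) {
        warning(sprintf(
          "participant %s: home unidentifiable (no night fixes); dropped",
          key$participant_id
        ), call. = FALSE)
        return(NULL)
      }
      cl <- cluster_locations(df, radius_m)
      df$cluster <- cl$assignment
      df |>
        dplyr::group_by(.data$date) |>
        dplyr::group_map(function(day, dkey) {
          tibble::tibble(
            participant_id = key$participant_id,
            date = dkey$date,
            homestay_h = daily_homestay(day, home$lat, home$lon, radius_m),
            entropy_nats = daily_entropy(tapply(day$dwell_s, day$cluster, sum)),
            distance_km = daily_distance(day, max_speed_kmh, min_segment_km),
            n_fixes = nrow(day),
            observed_span_h = sum(day$dwell_s) / 3600
          )
        }) |>
        dplyr::bind_rows()
    }) |>
    dplyr::bind_rows()
  if (nrow(out) == 0) {
    return(tibble::tibble(
      participant_id = character(), date = as.Date(character()),
      homestay_h = numeric(), entropy_nats = numeric(), distance_km = numeric(),
      n_fixes = integer(), observed_span_h = numeric()
    ))
  }
  out
}
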