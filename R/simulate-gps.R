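# GPS-level synthetic mobility: latent daily homestay fractions on a
# logit AR(1) process, contiguous home/anchor blocks within each day,
# Gaussian fix jitter, and whole-day missingness.

M_PER_DEG_LAT <- 111319.49

offset_latlon <- function(lat, lon, dx_m, dy_m) {
  list(
    lat = lat + dy_m / M_PER_DEG_LAT,
    lon = lon + dx_m / (M_PER_DEG_LAT * cos(lat * pi / 180))
  )
}

# Home plus n anchors, anchors 0.6-5 km from home and >= 0.5 km apart.
draw_locations <- function(config) {
  home_lat <- 40.55 + runif(1) * 0.3
  home_lon <- -74.15 + runif(1) * 0.3
  k <- config$n_anchor_locations
  lat <- numeric(k)
  lon <- numeric(k)
  for (j in seq_len(k)) {
    repeat {
      r <- runif(1, 600, 5000)
      th <- runif(1, 0, 2 * pi)
      p <- offset_latlon(home_lat, home_lon, r * cos(th), r * sin(th))
      if (j == 1 || all(haversine_km(p$lat, p$lon, lat[seq_len(j - 1)],
        lon[seq_len(j - 1)]) >= 0.5)) {
        lat[j] <- p$lat
        lon[j] <- p$lon
        break
      }
    }
  }
  list(home = c(lat = home_lat, lon = home_lon),
    anchors = cbind(lat = lat, lon = lon))
}

#' Simulate one participant's GPS fix stream
#'
#' Each simulated day places the participant at home for a latent fraction
#' of the day (logit-scale AR(1) across days with coefficient `ar1_rho`),
#' distributes the remaining time over anchor locations in contiguous
#' blocks, jitters every fix with isotropic Gaussian noise, keeps the
#' 02:00-06:00 window at the true home on `night_home_prob` of days, and
#' drops whole days with probability `gps_day_missing_prob`.
#'
#' @param config A [sim_config()].
#' @param participant_id Identifier for the output rows.
#' @param start_date First study day (a Date).
#' @param n_days Number of days to simulate (default `n_weeks * 7`).
#' @param home,anchors Optional fixed geography: `home` as
#'   `c(lat=, lon=)`, `anchors` as a 2-column (lat, lon) matrix. Anchors
#'   closer than `2 * home_radius_m` to home are rejected (homestay and
#'   entropy would be unidentifiable).
#' @param force_home_fraction Optional constant in (0, 1] overriding the
#'   latent process (1 = always home; used for degenerate checks).
#' @return List: `fixes` (tibble `participant_id`, `timestamp`, `lat`,
#'   `lon`, `accuracy_m`) and `truth` (`home`, `anchors`, per-day
#'   `home_fraction`, `true_path_km`, `true_entropy`, `observed`).
#' @export
simulate_mobility <- function(config, participant_id, start_date = as.Date("2023-01-04"),
                              n_days = config$n_weeks * 7, home = NULL,
                              anchors = NULL, force_home_fraction = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_anchor_locations < 1) stop("need at least one anchor location")
  if (is.null(home) || is.null(anchors)) {
    geo <- draw_locations(config)
    home <- geo$home
    anchors <- geo$anchors
  }
  d_home <- haversine_km(anchors[, "lat"], anchors[, "lon"],
    home[["lat"]], home[["lon"]]) * 1000
  if (any(d_home < 2 * config$home_radius_m)) {
    stop("anchor within 2 x home_radius_m of home; homestay/entropy unidentifiable",
      call. = FALSE)
  }

  n_fix <- config$fixes_per_day
  dt <- 86400 / n_fix
  tod_h <- (seq_len(n_fix) - 1) * dt / 3600
  night_idx <- which(tod_h >= 2 & tod_h < 6)
  # order non-night slots by circular distance from 04:00, so extra home
  # time accretes contiguously around the night block
  circ <- pmin(abs(tod_h - 4), 24 - abs(tod_h - 4))
  day_order <- setdiff(order(circ), night_idx)

  mu <- qlogis(0.6) + rnorm(1, 0, 0.5)
  z <- numeric(n_days)
  z[1] <- rnorm(1, 0, 0.8)
  for (t in seq_len(n_days - 1)) {
    z[t + 1] <- config$ar1_rho * z[t] + rnorm(1, 0, 0.8 * sqrt(1 - config$ar1_rho^2))
  }
  h_day <- if (is.null(force_home_fraction)) {
    plogis(mu + z)
  } else {
    rep(force_home_fraction, n_days)
  }
  observed <- runif(n_days) >= config$gps_day_missing_prob
  night_home <- runif(n_days) < config$night_home_prob

  all_lat <- c(home[["lat"]], anchors[, "lat"])
  all_lon <- c(home[["lon"]], anchors[, "lon"])
  k <- nrow(anchors)

  days <- vector("list", n_days)
  true_path <- numeric(n_days)
  true_entropy <- numeric(n_days)
  for (d in seq_len(n_days)) {
    loc <- rep(-1L, n_fix) # -1 = unassigned, 0 = home, 1..k = anchors
    n_home_target <- round(h_day[d] * n_fix)
    if (night_home[d]) {
      loc[night_idx] <- 0L
      extra <- max(0, n_home_target - length(night_idx))
    } else {
      loc[night_idx] <- sample.int(k, 1)
      extra <- min(n_home_target, n_fix - length(night_idx))
    }
    if (extra > 0) loc[day_order[seq_len(min(extra, length(day_order)))]] <- 0L
    away_left <- which(loc == -1L)
    if (length(away_left) > 0) {
      # contiguous runs of away time; each run split over 1-2 anchors
      runs <- split(away_left, cumsum(c(1, diff(away_left) != 1)))
      for (r in runs) {
        n_blocks <- min(length(r), sample.int(2, 1), k)
        cuts <- sort(sample.int(length(r) - 1, n_blocks - 1))
        sizes <- diff(c(0, cuts, length(r)))
        ank <- sample.int(k, n_blocks, replace = n_blocks > k)
        loc[r] <- rep(ank, sizes)
      }
    }
    if (!observed[d]) {
      p <- tabulate(loc + 1L, nbins = k + 1) / n_fix
      true_entropy[d] <- -sum(p[p > 0] * log(p[p > 0]))
      chg <- which(diff(loc) != 0)
      true_path[d] <- if (length(chg) > 0) {
        sum(haversine_km(all_lat[loc[chg] + 1], all_lon[loc[chg] + 1],
          all_lat[loc[chg + 1] + 1], all_lon[loc[chg + 1] + 1]))
      } else 0
      next
    }
    p <- tabulate(loc + 1L, nbins = k + 1) / n_fix
    true_entropy[d] <- -sum(p[p > 0] * log(p[p > 0]))
    chg <- which(diff(loc) != 0)
    true_path[d] <- if (length(chg) > 0) {
      sum(haversine_km(all_lat[loc[chg] + 1], all_lon[loc[chg] + 1],
        all_lat[loc[chg + 1] + 1], all_lon[loc[chg + 1] + 1]))
    } else 0
    lat0 <- all_lat[loc + 1L]
    lon0 <- all_lon[loc + 1L]
    jit <- offset_latlon(lat0, lon0,
      rnorm(n_fix, 0, config$jitter_sd_m), rnorm(n_fix, 0, config$jitter_sd_m))
    days[[d]] <- tibble::tibble(
      participant_id = participant_id,
      timestamp = as.POSIXct(start_date + (d - 1), tz = "UTC") +
        (seq_len(n_fix) - 1) * dt,
      lat = jit$lat, lon = jit$lon,
      accuracy_m = round(pmax(3, rnorm(n_fix, 12, 4)), 1)
    )
  }
  list(
    fixes = dplyr::bind_rows(days),
    truth = list(
      home = home, anchors = anchors, home_fraction = h_day,
      true_path_km = true_path, true_entropy = true_entropy,
      observed = observed,
      dates = start_date + seq_len(n_days) - 1
    )
  )
}

#' Simulate a complete synthetic study
#'
#' Generates the full four-table study — GPS fix streams, weekly surveys,
#' dated suicidal events, baseline covariates — plus ground truth. Latent
#' weekly features for the outcome model are computed from the complete
#' (pre-missingness) latent days, so the generative process matches what
#' the analysis pipeline assumes; observation missingness only hides data.
#'
#' @param config A [sim_config()].
#' @return List: `gps`, `esm`, `events`, `baseline` (tibbles matching the
#'   CSV schemas of [write_cohort()]), `ground_truth`, `config`.
#' @examples
#' cohort <- simulate_cohort(sim_config(n_participants = 3, n_weeks = 3, seed = 7))
#' dplyr::count(cohort$gps, participant_id)
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_local_seed(config$seed, {
    n <- config$n_participants
    ids <- sprintf("P%03d", seq_len(n))
    week0 <- as.Date("2023-01-04") # Wednesday
    mob <- purrr::map(ids, function(id) {
      simulate_mobility(config, id, start_date = week0)
    })
    names(mob) <- ids

    latent <- purrr::map(ids, function(id) {
      tr <- mob[[id]]$truth
      tibble::tibble(
        participant_id = id,
        date = tr$dates,
        h = tr$home_fraction * 24,
        ent = tr$true_entropy,
        dist = tr$true_path_km
      ) |>
        dplyr::mutate(
          week_index = as.integer((floor_wednesday(.data$date) - week0) / 7)
        ) |>
        dplyr::group_by(.data$participant_id, .data$week_index) |>
        dplyr::summarise(
          mean_homestay = mean(.data$h),
          mean_entropy = mean(.data$ent),
          mean_distance = mean(.data$dist),
          .groups = "drop"
        ) |>
        dplyr::mutate(week_start = week0 + 7 * .data$week_index)
    }) |>
      dplyr::bind_rows()

    sim <- simulate_outcomes(config, latent)

    baseline <- tibble::tibble(
      participant_id = ids,
      ssi = pmin(38, pmax(0, round(rnorm(n, 8, 7)))),
      site = sample(c("new_york", "pittsburgh"), n, replace = TRUE,
        prob = c(84, 102) / 186),
      sex = sample(c("male", "female"), n, replace = TRUE, prob = c(0.2, 0.8)),
      age = sample(13:18, n, replace = TRUE),
      device = sample(c("ios", "android"), n, replace = TRUE, prob = c(0.6, 0.4)),
      enrollment_date = week0
    )

    list(
      gps = dplyr::bind_rows(purrr::map(mob, "fixes")),
      esm = sim$esm,
      events = sim$events,
      baseline = baseline,
      ground_truth = c(sim$ground_truth, list(
        homes = purrr::map(mob, ~ .x$truth$home),
        truth = purrr::map(mob, "truth")
      )),
      config = config
    )
  })
}
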