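# Daily mobility features: distance, dwell, clustering, home inference,
# homestay, entropy.

test_that("haversine distance is exact on the equator and symmetric", {
  expect_equal(haversine_km(10, 20, 10, 20), 0)
  expect_equal(haversine_km(0, 0, 0, 1), 2 * pi * 6371.0088 / 360,
    tolerance = 1e-10)
  expect_equal(haversine_km(40.7, -74, 40.8, -73.9),
    haversine_km(40.8, -73.9, 40.7, -74))
  expect_error(haversine_km(95, 0, 0, 0), "latitude")
  expect_error(haversine_km(0, 181, 0, 0), "longitude")
})

test_that("haversine matches an independent spherical-law-of-cosines oracle", {
  set.seed(42)
  lat1 <- runif(100, -80, 80); lon1 <- runif(100, -179, 179)
  lat2 <- lat1 + runif(100, -2, 2); lon2 <- lon1 + runif(100, -2, 2)
  rad <- pi / 180
  slc <- 6371.0088 * acos(pmin(1,
    sin(lat1 * rad) * sin(lat2 * rad) +
      cos(lat1 * rad) * cos(lat2 * rad) * cos((lon2 - lon1) * rad)
  ))
  expect_equal(haversine_km(lat1, lon1, lat2, lon2), slc, tolerance = 1e-6)
})

test_that("dwell is the capped forward interval, last fix runs to midnight", {
  f <- make_fixes(rep(40.7, 5), rep(-74, 5), step_s = 600)
  d <- assign_dwell(f, gap_cap_min = 30)
  expect_equal(d$dwell_s[1:4], rep(600, 4))
  # 2-hour gap capped at 30 min
  f2 <- f
  f2$timestamp[5] <- f2$timestamp[4] + 7200
  d2 <- assign_dwell(f2, gap_cap_min = 30)
  expect_equal(d2$dwell_s[4], 1800)
  # unordered input names the offender
  f3 <- f
  f3$timestamp[3] <- f3$timestamp[2]
  expect_error(assign_dwell(f3), "not strictly increasing.*P1")
})

test_that("sum of dwell never exceeds the observed span (enumerated streams)", {
  # all gap patterns from a small alphabet, exhaustively
  gaps <- expand.grid(g1 = c(60, 600, 3600), g2 = c(60, 600, 3600),
    g3 = c(60, 600, 7200))
  for (i in seq_len(nrow(gaps))) {
    ts <- as.POSIXct("2023-01-04 10:00:00", tz = "UTC") +
      cumsum(c(0, as.numeric(gaps[i, ])))
    f <- tibble::tibble(participant_id = "P1", timestamp = ts,
      lat = 40.7, lon = -74)
    d <- assign_dwell(f, gap_cap_min = 30)
    span_s <- sum(pmin(as.numeric(diff(ts), units = "secs"), 1800)) + 1800
    expect_lte(sum(d$dwell_s), span_s)
    expect_lte(sum(d$dwell_s), 24 * 3600)
  }
})

test_that("greedy clustering separates distant sites and merges nearby fixes", {
  base <- c(lat = 40.7, lon = -74)
  near <- move_m(base["lat"], base["lon"], east_m = runif(20, -50, 50),
    north_m = runif(20, -50, 50))
  f1 <- make_fixes(near$lat, near$lon)
  f1$dwell_s <- 600
  cl1 <- cluster_locations(f1, radius_m = 200)
  expect_equal(nrow(cl1$clusters), 1L)

  far <- move_m(base["lat"], base["lon"], east_m = 1000)
  f2 <- make_fixes(c(rep(base["lat"], 5), rep(far$lat, 5)),
    c(rep(base["lon"], 5), rep(far$lon, 5)))
  f2$dwell_s <- 600
  cl2 <- cluster_locations(f2, radius_m = 200)
  expect_equal(nrow(cl2$clusters), 2L)
  expect_equal(cl2$assignment, rep(1:2, each = 5))
  expect_equal(cluster_locations(f2[0, ], 200)$clusters |> nrow(), 0L)
})

test_that("clustering recovers the generating site for >= 99% of jittered fixes", {
  cfg <- sim_config(n_participants = 1, n_weeks = 2, gps_day_missing_prob = 0,
    seed = 21)
  mob <- simulate_mobility(cfg, "P1")
  f <- assign_dwell(mob$fixes)
  cl <- cluster_locations(f, radius_m = 200)
  truth_lat <- c(mob$truth$home[["lat"]], mob$truth$anchors[, "lat"])
  truth_lon <- c(mob$truth$home[["lon"]], mob$truth$anchors[, "lon"])
  # nearest-true-site oracle per fix vs nearest true site of its centroid
  site_of_fix <- apply(
    sapply(seq_along(truth_lat), function(s)
      haversine_km(f$lat, f$lon, truth_lat[s], truth_lon[s])), 1, which.min)
  site_of_cluster <- apply(
    sapply(seq_along(truth_lat), function(s)
      haversine_km(cl$clusters$centroid_lat, cl$clusters$centroid_lon,
        truth_lat[s], truth_lon[s])), 1, which.min)
  agree <- site_of_cluster[cl$assignment] == site_of_fix
  expect_gte(mean(agree), 0.99)
})

test_that("home inference follows night dwell with the stated tie-breaks", {
  # all night fixes at one site -> that site
  home <- c(lat = 40.7, lon = -74)
  away <- move_m(home["lat"], home["lon"], east_m = 1500)
  f <- make_fixes(
    c(rep(home["lat"], 24), rep(away$lat, 20)),
    c(rep(home["lon"], 24), rep(away$lon, 20)),
    start = "2023-01-04 02:00:00", step_s = 600
  ) # home covers 02:00-06:00; away block daytime only
  f <- assign_dwell(f)
  h <- estimate_home(f)
  expect_lt(haversine_km(h$lat, h$lon, home["lat"], home["lon"]), 0.05)

  # exact night tie: more-visited cluster wins
  siteA <- home
  siteB <- unlist(move_m(home["lat"], home["lon"], east_m = 2000))
  ts <- function(hms, day = 4) as.POSIXct(sprintf("2023-01-%02d %s", day, hms),
    tz = "UTC")
  f2 <- tibble::tibble(
    participant_id = "P1",
    timestamp = c(ts("03:00:00"), ts("03:30:00"),
      ts("12:00:00"), ts("12:30:00"), ts("13:00:00")),
    lat = c(siteA["lat"], siteB[1], siteB[1], siteB[1], siteA["lat"]),
    lon = c(siteA["lon"], siteB[2], siteB[2], siteB[2], siteA["lon"])
  )
  f2 <- assign_dwell(f2) # night dwell: A 30 min, B 30 min; B has more all-day
  h2 <- estimate_home(f2)
  expect_lt(haversine_km(h2$lat, h2$lon, siteB[1], siteB[2]), 0.05)

  # no night fixes at all -> explicit error
  f3 <- make_fixes(rep(40.7, 5), rep(-74, 5), start = "2023-01-04 10:00:00")
  f3 <- assign_dwell(f3)
  expect_error(estimate_home(f3), "home unidentifiable")
})

test_that("home inference recovers true homes within 200 m on a synthetic cohort", {
  cfg <- sim_config(n_participants = 5, n_weeks = 2, seed = 31)
  co <- simulate_cohort(cfg)
  for (id in names(co$ground_truth$homes)) {
    f <- assign_dwell(dplyr::filter(co$gps, participant_id == id))
    h <- estimate_home(f)
    true <- co$ground_truth$homes[[id]]
    expect_lt(haversine_km(h$lat, h$lon, true[["lat"]], true[["lon"]]), 0.2)
  }
})

test_that("daily homestay equals the brute-force dwell sum within the radius", {
  home <- c(lat = 40.7, lon = -74)
  inside <- move_m(home["lat"], home["lon"], east_m = 150)
  outside <- move_m(home["lat"], home["lon"], east_m = 500)
  f <- make_fixes(
    c(rep(home["lat"], 3), inside$lat, rep(outside$lat, 4)),
    c(rep(home["lon"], 3), inside$lon, rep(outside$lon, 4))
  )
  f <- assign_dwell(f)
  hs <- daily_homestay(f, home["lat"], home["lon"], radius_m = 200)
  # independent per-fix filter
  manual <- sum(f$dwell_s[
    haversine_km(f$lat, f$lon, home["lat"], home["lon"]) <= 0.2
  ]) / 3600
  expect_equal(hs, manual)
  expect_equal(manual, 4 * 600 / 3600)
  # all inside -> full span; none inside -> 0
  expect_equal(daily_homestay(f[1:4, ], home["lat"], home["lon"]),
    sum(f$dwell_s[1:4]) / 3600)
  expect_equal(daily_homestay(f[5:8, ], home["lat"], home["lon"]), 0)
})

test_that("daily entropy matches hand-computed Shannon values and bounds", {
  expect_equal(daily_entropy(c(3600)), 0)
  expect_equal(daily_entropy(rep(900, 4)), log(4))
  expect_equal(daily_entropy(c(0.5, 0.25, 0.25) * 7200), 1.5 * log(2))
  expect_equal(daily_entropy(c(1000, 0, 500)), daily_entropy(c(1000, 500)))
  expect_true(is.na(daily_entropy(c(0, 0))))
  # 0 <= H <= ln K on random compositions
  set.seed(7)
  for (i in 1:50) {
    k <- sample(1:6, 1)
    w <- rgamma(k, 1)
    h <- daily_entropy(w)
    expect_gte(h, 0)
    expect_lte(h, log(k) + 1e-12)
  }
})

test_that("daily distance is additive, robust to filters, zero for single fixes", {
  home <- c(lat = 40.7, lon = -74)
  out5 <- move_m(home["lat"], home["lon"], north_m = 5000)
  f <- make_fixes(
    c(home["lat"], out5$lat, out5$lat, home["lat"]),
    c(home["lon"], out5$lon, out5$lon, home["lon"]),
    step_s = 1800
  )
  expect_equal(daily_distance(f), 10, tolerance = 1e-3)
  expect_equal(daily_distance(f[1, ]), 0)
  expect_equal(daily_distance(f[0, ]), 0)
  # a 600 km teleport in 10 minutes is dropped by the speed filter
  tele <- f
  tele$lat[3] <- tele$lat[3] + 5
  expect_lt(daily_distance(tele, max_speed_kmh = 300), 20)
  expect_gt(daily_distance(tele), 1000)
})

test_that("noisy synthetic tracks recover the generating path length within 5%", {
  cfg <- sim_config(n_participants = 1, n_weeks = 2, gps_day_missing_prob = 0,
    jitter_sd_m = 25, night_home_prob = 1, seed = 77)
  mob <- simulate_mobility(cfg, "P1")
  f <- assign_dwell(mob$fixes)
  rel_err <- sapply(split(f, f$date), function(day) {
    d_obs <- daily_distance(day, max_speed_kmh = 300, min_segment_km = 0.15)
    d_true <- mob$truth$true_path_km[mob$truth$dates == day$date[1]]
    abs(d_obs - d_true) / max(d_true, 0.5)
  })
  expect_lt(median(rel_err), 0.05)
  expect_lt(mean(rel_err), 0.05)
})

test_that("feature invariants hold: bounds, translation, purity", {
  cfg <- sim_config(n_participants = 2, n_weeks = 2, seed = 55)
  co <- simulate_cohort(cfg)
  df1 <- daily_features(co$gps)
  # bounds
  expect_true(all(df1$homestay_h >= 0))
  expect_true(all(df1$homestay_h <= df1$observed_span_h + 1e-9))
  expect_true(all(df1$observed_span_h <= 24 + 1e-9))
  expect_true(all(df1$entropy_nats >= 0, na.rm = TRUE))
  expect_true(all(df1$distance_km >= 0))
  expect_true(all(df1$distance_km[df1$n_fixes <= 1] == 0))
  # purity: identical rerun
  df2 <- daily_features(co$gps)
  expect_identical(df1, df2)
  # longitude translation leaves homestay/entropy unchanged, distance ~same
  gps_shift <- dplyr::mutate(co$gps, lon = lon + 10)
  df3 <- daily_features(gps_shift)
  expect_equal(df3$homestay_h, df1$homestay_h, tolerance = 1e-9)
  expect_equal(df3$entropy_nats, df1$entropy_nats, tolerance = 1e-9)
  expect_equal(df3$distance_km, df1$distance_km, tolerance = 1e-6)
})

test_that("zero-jitter, no-missingness homestay matches the generative fraction", {
  cfg <- sim_config(n_participants = 1, n_weeks = 2, gps_day_missing_prob = 0,
    jitter_sd_m = 0, night_home_prob = 1, seed = 3)
  mob <- simulate_mobility(cfg, "P1")
  f <- assign_dwell(mob$fixes)
  h <- estimate_home(f)
  per_day <- sapply(split(f, f$date), function(day)
    daily_homestay(day, h$lat, h$lon))
  fix_interval_h <- 24 / cfg$fixes_per_day
  expect_lt(max(abs(per_day - 24 * mob$truth$home_fraction)), fix_interval_h)
})

test_that("an always-home participant has homestay = span and ~zero distance", {
  cfg <- sim_config(n_participants = 1, n_weeks = 2, gps_day_missing_prob = 0,
    jitter_sd_m = 0, night_home_prob = 1, seed = 5)
  mob <- simulate_mobility(cfg, "P1", force_home_fraction = 1)
  df <- daily_features(mob$fixes, min_segment_km = 0)
  expect_equal(df$homestay_h, df$observed_span_h, tolerance = 1e-9)
  expect_true(all(df$distance_km < 0.01))
})
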