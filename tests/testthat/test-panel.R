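# Weekly aggregation, event merging, ideation flagging, within/between
# decomposition and lagged panel assembly.

test_that("weekly aggregation means available days and applies the 3-day rule", {
  enr <- tibble::tibble(participant_id = "P1",
    enrollment_date = as.Date("2023-01-04"))
  daily <- tibble::tibble(
    participant_id = "P1",
    date = as.Date("2023-01-04") + 0:6,
    homestay_h = 10, entropy_nats = 0.5, distance_km = 3,
    n_fixes = 100L, observed_span_h = 24
  )
  wk <- aggregate_weekly(daily, enr, n_weeks = 2)
  expect_equal(wk$mean_homestay[wk$week_index == 0], 10)
  expect_equal(wk$n_gps_days[wk$week_index == 0], 7L)
  expect_true(all(weekdays(wk$week_start) == "Wednesday"))
  # 2 GPS days -> features missing, row retained
  wk2 <- aggregate_weekly(daily[1:2, ], enr, n_weeks = 1)
  expect_equal(nrow(wk2), 1L)
  expect_true(is.na(wk2$mean_homestay))
  expect_equal(wk2$n_gps_days, 2L)
})

test_that("weekly means match naive recomputation under random availability", {
  set.seed(11)
  enr <- tibble::tibble(participant_id = c("A", "B"),
    enrollment_date = as.Date("2023-01-04"))
  daily <- tidyr::expand_grid(
    participant_id = c("A", "B"),
    date = as.Date("2023-01-04") + 0:27
  ) |>
    dplyr::slice_sample(prop = 0.7) |>
    dplyr::mutate(
      homestay_h = runif(dplyr::n(), 0, 24),
      entropy_nats = runif(dplyr::n(), 0, 2),
      distance_km = runif(dplyr::n(), 0, 30),
      n_fixes = 100L, observed_span_h = 24
    )
  wk <- aggregate_weekly(daily, enr, n_weeks = 4)
  # naive oracle
  naive <- daily |>
    dplyr::mutate(wi = as.integer((as.numeric(date - as.Date("2023-01-04"))) %/% 7))
  for (i in seq_len(nrow(wk))) {
    sub <- naive[naive$participant_id == wk$participant_id[i] &
      naive$wi == wk$week_index[i], ]
    if (nrow(sub) >= 3) {
      expect_equal(wk$mean_homestay[i], mean(sub$homestay_h))
      expect_equal(wk$mean_distance[i], mean(sub$distance_km))
    } else {
      expect_true(is.na(wk$mean_homestay[i]))
    }
  }
  # out-of-window rows warn and drop
  late <- daily
  late$date[1] <- as.Date("2023-06-01")
  expect_warning(aggregate_weekly(late, enr, n_weeks = 4), "outside the study window")
})

test_that("event merging follows the 7-day rule and is idempotent", {
  ev <- tibble::tibble(
    participant_id = "P1",
    event_date = as.Date("2023-02-01") + c(0, 2, 19),
    event_type = c("actual_attempt", "ed_visit", "hospitalization")
  )
  m <- merge_events(ev)
  # ED visit 2 days after the attempt merges; hospitalization day 19 does not
  expect_equal(nrow(m), 2L)
  expect_equal(m$event_date[1], as.Date("2023-02-01"))
  expect_equal(m$n_merged[1], 2L)
  expect_equal(m$event_type, c("actual_attempt", "hospitalization"))
  # attempts never merge with each other
  ev2 <- tibble::tibble(
    participant_id = "P1",
    event_date = as.Date("2023-02-01") + c(0, 3),
    event_type = c("actual_attempt", "aborted_attempt")
  )
  expect_equal(nrow(merge_events(ev2)), 2L)
  # idempotent
  m2 <- merge_events(dplyr::select(m, -"n_merged") |>
    dplyr::mutate(n_merged = NULL))
  expect_equal(m2$event_date, m$event_date)
  expect_error(merge_events(tibble::tibble(
    participant_id = "P1", event_date = as.Date("2023-01-01"),
    event_type = "overdose"
  )), "unknown event_type")
})

test_that("merged count equals an exhaustive pairwise-window oracle on 33 records", {
  set.seed(23)
  n_att <- 20
  att <- tibble::tibble(
    participant_id = sample(sprintf("P%02d", 1:12), n_att, replace = TRUE),
    event_date = as.Date("2023-01-04") + sample(0:150, n_att, replace = TRUE),
    event_type = sample(c("actual_attempt", "aborted_attempt",
      "interrupted_attempt"), n_att, replace = TRUE)
  )
  extra <- tibble::tibble(
    participant_id = c(att$participant_id[1:8], sample(att$participant_id, 5)),
    event_date = c(att$event_date[1:8] + sample(0:7, 8, replace = TRUE),
      as.Date("2023-01-04") + sample(0:150, 5, replace = TRUE)),
    event_type = sample(c("ed_visit", "hospitalization"), 13, replace = TRUE)
  )
  ev <- dplyr::bind_rows(att, extra)
  expect_equal(nrow(ev), 33L)
  m <- merge_events(ev)
  # oracle: a non-attempt record is absorbed iff some same-participant
  # attempt lies in [date - 7, date]
  absorbed <- purrr::map_lgl(seq_len(nrow(ev)), function(i) {
    if (ev$event_type[i] %in% c("actual_attempt", "aborted_attempt",
      "interrupted_attempt")) {
      return(FALSE)
    }
    any(att$participant_id == ev$participant_id[i] &
      att$event_date >= ev$event_date[i] - 7 &
      att$event_date <= ev$event_date[i])
  })
  expect_equal(nrow(m), sum(!absorbed))
})

test_that("ideation flag applies the >=4-or-plan rule and missingness", {
  esm <- tibble::tibble(
    responded = c(1, 1, 1, 0, 1),
    ideation_1to5 = c(4L, 3L, 2L, NA, 5L),
    plan_yn = c("no", "yes", "no", NA, "yes")
  )
  expect_equal(flag_ideation(esm), c(1L, 1L, 0L, NA, 1L))
  bad <- tibble::tibble(responded = 1, ideation_1to5 = 7L, plan_yn = "no")
  expect_error(flag_ideation(bad), "ideation_1to5 outside 1-5")
})

test_that("decomposition matches the hand-worked two-participant example", {
  wk <- make_weekly(list(A = c(10, 12), B = c(20, 26)))
  dec <- decompose_weekly(wk)
  # person means 11, 23; centered (-1, 1, -3, 3)
  centered <- c(-1, 1, -3, 3)
  sd_within <- sd(centered)            # pooled SD of all centered values
  sd_between <- sd(c(11, 23))          # SD of person means
  expect_equal(dec$hw_within, centered / sd_within)
  expect_equal(dec$hw_between,
    (rep(c(11, 23), each = 2) - 17) / sd_between)
  # constant feature within one participant -> within terms 0
  wk2 <- make_weekly(list(A = c(5, 5, 5), B = c(1, 2, 3)))
  dec2 <- decompose_weekly(wk2)
  expect_equal(dec2$hw_within[dec2$participant_id == "A"], rep(0, 3))
})

test_that("centered values sum to ~0 per participant on arbitrary input", {
  set.seed(99)
  wk <- make_weekly(list(
    A = runif(8, 0, 24), B = runif(5, 0, 24), C = runif(12, 0, 24)
  ))
  dec <- decompose_weekly(wk)
  sums <- tapply(dec$hw_within, dec$participant_id, sum)
  expect_true(all(abs(sums) < 1e-9 * table(dec$participant_id)))
  # between terms constant within participant
  expect_true(all(tapply(dec$hw_between, dec$participant_id,
    function(x) max(x) - min(x)) == 0))
})

test_that("participants with fewer than two usable weeks get missing within terms", {
  wk <- make_weekly(list(A = c(10, 12, 14), B = 20))
  dec <- decompose_weekly(wk)
  expect_true(all(is.na(dec$hw_within[dec$participant_id == "B"])))
  expect_true(all(dec$flag_few_weeks[dec$participant_id == "B"]))
  expect_false(any(is.na(dec$hw_within[dec$participant_id == "A"])))
})

test_that("lagged panel pairs outcome week T with features from week T-L", {
  wk <- make_weekly(list(A = c(10, 12, 11, 14, 9, 13), B = c(6, 7, 8, 6, 7, 8)))
  dec <- decompose_weekly(wk)
  dec$event_flag <- c(0L, 0L, 0L, 0L, 0L, 1L, rep(0L, 6))
  dec$responded <- 1L
  dec$ideation_flag <- 0L
  pan <- build_panel(dec, lag = 1, outcome = "event")
  # week 5 outcome pairs with week 4 features
  row5 <- pan[pan$week_index == 5 & pan$participant_id == "A", ]
  expect_equal(row5$outcome_event, 1L)
  expect_equal(row5$hw_within,
    dec$hw_within[dec$week_index == 4 & dec$participant_id == "A"])
  expect_equal(row5$weeks_since_baseline, 5)
  # lagged features missing -> week contributes no row
  dec2 <- dec
  dec2$hw_within[dec2$week_index == 4 & dec2$participant_id == "A"] <- NA
  pan2 <- build_panel(dec2, lag = 1, outcome = "event")
  expect_false(5 %in% pan2$week_index[pan2$participant_id == "A"])
  expect_error(build_panel(dec, lag = -1), "lag")
})

test_that("no panel row uses feature data from the outcome week or later (L >= 1)", {
  sim <- simulate_panel(sim_config(n_participants = 25, n_weeks = 10, seed = 17))
  dec <- sim$decomposed
  for (L in 1:3) {
    pan <- build_panel(dec, lag = L, outcome = "event")
    joined <- dplyr::inner_join(
      pan,
      dplyr::select(dec, "participant_id", src_week = "week_index", "hw_within"),
      by = c("participant_id"),
      relationship = "many-to-many"
    ) |>
      dplyr::filter(.data$hw_within.y == .data$hw_within.x, !is.na(.data$hw_within.x))
    # every matching source week lies at least L weeks before the outcome
    expect_true(all(joined$week_index - joined$src_week >= L |
      abs(joined$hw_within.x) < 1e-12))
  }
})

test_that("ideation panel keeps only responded weeks, events panel keeps all", {
  sim <- simulate_panel(sim_config(n_participants = 40, n_weeks = 12, seed = 29))
  dec <- sim$decomposed
  ev <- build_panel(dec, lag = 1, outcome = "event")
  id <- build_panel(dec, lag = 1, outcome = "ideation")
  expect_true(all(!is.na(id$outcome_ideation)))
  expect_lt(nrow(id), nrow(ev))
  # response rate ~0.41 shrinks the ideation panel proportionally
  expect_equal(nrow(id) / nrow(ev), 0.41, tolerance = 0.15)
})

test_that("rebuilding without one participant only shifts others via pooled SDs", {
  wk <- make_weekly(list(A = c(10, 12, 14), B = c(8, 9, 10), C = c(20, 24, 22)))
  dec_all <- decompose_weekly(wk)
  dec_sub <- decompose_weekly(wk[wk$participant_id != "C", ])
  sc_all <- attr(dec_all, "scaling")$hw
  sc_sub <- attr(dec_sub, "scaling")$hw
  a_all <- dec_all$hw_within[dec_all$participant_id == "A"]
  a_sub <- dec_sub$hw_within[dec_sub$participant_id == "A"]
  # same centered values, different pooled SD only
  expect_equal(a_all * sc_all$sd_within, a_sub * sc_sub$sd_within)
})

test_that("reversed panel pairs event at T-1 with the feature at T", {
  wk <- make_weekly(list(A = c(10, 12, 11, 14)))
  dec <- decompose_weekly(wk)
  dec$event_flag <- c(0L, 1L, 0L, 0L)
  rp <- build_reversed_panel(dec, "hw_within")
  expect_equal(rp$event_prev[rp$week_index == 2], 1L)
  expect_equal(rp$feature_value[rp$week_index == 2],
    dec$hw_within[dec$week_index == 2])
  expect_equal(nrow(rp), 3L) # weeks 1..3 have a preceding week
})
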