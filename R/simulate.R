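# Synthetic study generator: GPS fix streams, weekly surveys, suicidal
# events and baseline covariates with known ground-truth parameters, so
# every downstream stage is testable without access to raw study data.

#' Simulation configuration
#'
#' Defaults emulate the study conditions the pipeline assumes: 186
#' participants followed ~26 weeks, GPS available on ~75% of days, weekly
#' surveys answered on ~41% of weeks, a rare (~1% per person-week) binary
#' event outcome driven by a within-person homestay effect of log(2) per
#' SD, and a per-participant Normal random intercept.
#'
#' @param n_participants,n_weeks Cohort size and follow-up length.
#' @param fixes_per_day GPS sampling cadence (144 = one fix / 10 min).
#' @param gps_day_missing_prob Probability a whole day of GPS is missing.
#' @param esm_response_prob Probability a weekly survey is answered.
#' @param home_radius_m Homestay/cluster radius in metres.
#' @param n_anchor_locations Non-home anchor locations per participant.
#' @param within_homestay_logor Generative log-odds per 1 SD within-person
#'   homestay increase (default log 2).
#' @param between_terms_logor Named vector of generative between-person
#'   log-odds (`hw`, `en`, `di`), default all 0.
#' @param random_intercept_sd SD of the participant random intercept on
#'   the log-odds scale (default 0.6).
#' @param event_intercept Log-odds intercept of the weekly event model
#'   (default -4.7, about a 1% weekly rate).
#' @param ideation_intercept Log-odds intercept of the weekly ideation
#'   model (default -2.75, clinically meaningful ideation on a minority of
#'   responded weeks).
#' @param ar1_rho Autocorrelation of the latent (logit-scale) daily
#'   homestay process, in (-1, 1).
#' @param jitter_sd_m Isotropic GPS noise SD in metres (<= 25).
#' @param night_home_prob Probability a day's 02:00-06:00 window is spent
#'   at the true home (>= 0.9 keeps the night-window home rule
#'   identifiable).
#' @param seed Integer seed; fixing it makes the whole cohort reproducible.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_participants = 186, n_weeks = 26, fixes_per_day = 144,
                       gps_day_missing_prob = 0.25, esm_response_prob = 0.41,
                       home_radius_m = 200, n_anchor_locations = 4,
                       within_homestay_logor = log(2),
                       between_terms_logor = c(hw = 0, en = 0, di = 0),
                       random_intercept_sd = 0.6, event_intercept = -4.7,
                       ideation_intercept = -2.75, ar1_rho = 0.4,
                       jitter_sd_m = 15, night_home_prob = 0.95, seed = 1) {
  cfg <- list(
    n_participants = n_participants, n_weeks = n_weeks,
    fixes_per_day = fixes_per_day,
    gps_day_missing_prob = gps_day_missing_prob,
    esm_response_prob = esm_response_prob, home_radius_m = home_radius_m,
    n_anchor_locations = n_anchor_locations,
    within_homestay_logor = within_homestay_logor,
    between_terms_logor = between_terms_logor,
    random_intercept_sd = random_intercept_sd,
    event_intercept = event_intercept,
    ideation_intercept = ideation_intercept,
    ar1_rho = ar1_rho, jitter_sd_m = jitter_sd_m,
    night_home_prob = night_home_prob, seed = seed
  )
  probs <- c(gps_day_missing_prob, esm_response_prob, night_home_prob)
  stopifnot(
    n_participants >= 1, n_weeks >= 2, fixes_per_day >= 24,
    all(probs >= 0 & probs <= 1), ar1_rho > -1, ar1_rho < 1,
    n_anchor_locations >= 1, random_intercept_sd >= 0,
    jitter_sd_m >= 0, jitter_sd_m <= 25,
    all(c("hw", "en", "di") %in% names(between_terms_logor))
  )
  structure(cfg, class = "sim_config")
}

true_beta_vector <- function(config) {
  c(
    "(Intercept)" = config$event_intercept,
    hw_within = config$within_homestay_logor,
    en_within = 0, di_within = 0,
    hw_between = unname(config$between_terms_logor[["hw"]]),
    en_between = unname(config$between_terms_logor[["en"]]),
    di_between = unname(config$between_terms_logor[["di"]]),
    weeks_since_baseline = 0
  )
}

# Evaluate, then restore, the global RNG state.
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

# Marginal event probability at x = 0, integrating over the random
# intercept with Gauss-Hermite quadrature.
marginal_rate <- function(intercept, sigma_u, n_quad = 41) {
  gh <- gauss_hermite(n_quad)
  sum(gh$weights / sqrt(pi) * plogis(intercept + sqrt(2) * sigma_u * gh$nodes))
}

#' Simulate weekly outcomes from latent weekly features
#'
#' The generative inverse of the analysis model. Latent weekly features
#' (complete, before observation missingness) are decomposed into the same
#' within-/between-person standardized terms the analysis uses; the week-T
#' event indicator is then Bernoulli with log-odds
#' `event_intercept + sum(true_beta * x[T-1]) + u_i`,
#' `u_i ~ N(0, random_intercept_sd^2)`. Ideation outcomes are generated on
#' responded weeks only (response is Bernoulli with `esm_response_prob`),
#' from `ideation_intercept + u_i`.
#'
#' @param config A [sim_config()].
#' @param latent_weekly Tibble with `participant_id`, `week_index`,
#'   `week_start`, `mean_homestay`, `mean_entropy`, `mean_distance` for
#'   every participant-week.
#' @return List: `weekly` (latent features + `event_flag`, `responded`,
#'   `ideation_flag`, within/between terms), `events` (dated event
#'   records), `esm` (survey table), `ground_truth` (`true_beta`,
#'   `true_sigma_u`, `u`, per-week linear predictors).
#' @export
simulate_outcomes <- function(config, latent_weekly) {
  stopifnot(inherits(config, "sim_config"))
  need <- c("participant_id", "week_index", "week_start",
    "mean_homestay", "mean_entropy", "mean_distance")
  stopifnot(all(need %in% names(latent_weekly)))
  if (anyNA(latent_weekly[, need])) {
    stop("latent weekly features must exist for all participant-weeks",
      call. = FALSE)
  }
  rate <- marginal_rate(config$event_intercept, config$random_intercept_sd)
  if (rate > 0.2) {
    stop(sprintf(
      "implied marginal event rate %.1f%% exceeds the 20%% rare-event bound;
check event_intercept / random_intercept_sd", 100 * rate
    ), call. = FALSE)
  }

  wk <- latent_weekly |>
    dplyr::mutate(n_gps_days = 7L) |>
    decompose_weekly() |>
    # degenerate cohorts (a single participant, or constant features) have
    # undefined scaling SDs; their design contribution is zero, not NA
    dplyr::mutate(dplyr::across(
      dplyr::ends_with("_within") | dplyr::ends_with("_between"),
      ~ dplyr::coalesce(.x, 0)
    ))
  beta <- true_beta_vector(config)

  ids <- unique(wk$participant_id)
  u <- setNames(rnorm(length(ids), 0, config$random_intercept_sd), ids)

  wk <- wk |>
    dplyr::arrange(.data$participant_id, .data$week_index) |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::mutate(
      eta_event = beta[["(Intercept)"]] +
        dplyr::lag(beta[["hw_within"]] * .data$hw_within +
          beta[["en_within"]] * .data$en_within +
          beta[["di_within"]] * .data$di_within, default = 0) +
        beta[["hw_between"]] * .data$hw_between +
        beta[["en_between"]] * .data$en_between +
        beta[["di_between"]] * .data$di_between +
        beta[["weeks_since_baseline"]] * .data$week_index +
        u[as.character(.data$participant_id[1])]
    ) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      event_flag = rbinom(dplyr::n(), 1, plogis(.data$eta_event)),
      responded = rbinom(dplyr::n(), 1, config$esm_response_prob),
      eta_ideation = config$ideation_intercept +
        u[as.character(.data$participant_id)],
      ideation_flag = ifelse(.data$responded == 1,
        rbinom(dplyr::n(), 1, plogis(.data$eta_ideation)), NA_integer_
      )
    )

  events <- wk |>
    dplyr::filter(.data$event_flag == 1) |>
    dplyr::mutate(
      event_date = .data$week_start + sample(0:6, dplyr::n(), replace = TRUE),
      event_type = sample(ATTEMPT_TYPES, dplyr::n(), replace = TRUE,
        prob = c(0.4, 0.6, 0.2) / 1.2
      )
    ) |>
    dplyr::select("participant_id", "event_date", "event_type")
  # companion ED visits / hospitalizations within 7 days after an attempt,
  # so the event-merging rule has work to do
  if (nrow(events) > 0) {
    comp <- events[runif(nrow(events)) < 0.35, , drop = FALSE]
    if (nrow(comp) > 0) {
      comp <- comp |>
        dplyr::mutate(
          event_date = .data$event_date + sample(0:7, dplyr::n(), replace = TRUE),
          event_type = sample(c("ed_visit", "hospitalization"), dplyr::n(),
            replace = TRUE
          )
        )
      events <- dplyr::bind_rows(events, comp) |>
        dplyr::arrange(.data$participant_id, .data$event_date)
    }
  }

  esm <- wk |>
    dplyr::mutate(
      survey_date = .data$week_start + 7,
      ideation_1to5 = dplyr::case_when(
        .data$responded == 0 ~ NA_integer_,
        .data$ideation_flag == 1 ~ sample(4:5, dplyr::n(), replace = TRUE,
          prob = c(0.7, 0.3)),
        TRUE ~ sample(1:3, dplyr::n(), replace = TRUE, prob = c(0.6, 0.3, 0.1))
      ),
      plan_yn = dplyr::case_when(
        .data$responded == 0 ~ NA_character_,
        .data$ideation_flag == 1 & runif(dplyr::n()) < 0.3 ~ "yes",
        TRUE ~ "no"
      ),
      attempt_yn = ifelse(.data$responded == 1,
        ifelse(.data$event_flag == 1 & runif(dplyr::n()) < 0.6, "yes", "no"),
        NA_character_
      )
    ) |>
    dplyr::select(
      "participant_id", "survey_date", "responded",
      "ideation_1to5", "plan_yn", "attempt_yn"
    )

  list(
    weekly = wk,
    events = events,
    esm = esm,
    ground_truth = list(
      true_beta = beta,
      true_sigma_u = config$random_intercept_sd,
      u = u,
      marginal_event_rate = rate
    )
  )
}

# Latent weekly features: person means plus AR(1) weekly deviations, with
# negative homestay-entropy/distance coupling as seen in mobility data.
latent_weekly_features <- function(config) {
  n <- config$n_participants
  W <- config$n_weeks
  week0 <- as.Date("2023-01-04") # a Wednesday
  ids <- sprintf("P%03d", seq_len(n))
  ar1 <- function(rho, W, sd) {
    z <- numeric(W)
    z[1] <- rnorm(1, 0, sd)
    for (t in seq_len(W - 1)) {
      z[t + 1] <- rho * z[t] + rnorm(1, 0, sd * sqrt(1 - rho^2))
    }
    z
  }
  purrr::map(seq_len(n), function(i) {
    hw_dev <- ar1(config$ar1_rho, W, 1.6)
    en_dev <- -0.5 * hw_dev / 1.6 * 0.25 + rnorm(W, 0, 0.25 * sqrt(0.75))
    di_dev <- -0.4 * hw_dev / 1.6 * 5 + rnorm(W, 0, 5 * sqrt(0.84))
    tibble::tibble(
      participant_id = ids[i],
      week_index = 0:(W - 1),
      week_start = week0 + 7 * (0:(W - 1)),
      mean_homestay = pmin(24, pmax(0, rnorm(1, 14, 2.5) + hw_dev)),
      mean_entropy = pmax(0, rnorm(1, 1.0, 0.3) + en_dev),
      mean_distance = pmax(0, rnorm(1, 15, 6) + di_dev)
    )
  }) |>
    dplyr::bind_rows()
}

#' Fast panel-level synthetic study
#'
#' Skips the GPS layer entirely: draws latent weekly features, simulates
#' outcomes via [simulate_outcomes()], applies week-level GPS observation
#' missingness (a week is unusable when fewer than 3 of its 7 days have
#' GPS, given the configured day-missing probability), and assembles the
#' lag-1 event panel. This is the workhorse for parameter-recovery, type-I
#' error and validation simulations.
#'
#' @param config A [sim_config()].
#' @param lag Feature lag for the convenience panel (default 1).
#' @return List: `decomposed` (weekly table with outcomes and observed,
#'   possibly-missing features re-decomposed), `panel` (lag-`lag` event
#'   panel), `ground_truth`.
#' @export
simulate_panel <- function(config, lag = 1) {
  stopifnot(inherits(config, "sim_config"))
  with_local_seed(config$seed, {
    latent <- latent_weekly_features(config)
    sim <- simulate_outcomes(config, latent)
    n_gps_days <- rbinom(nrow(sim$weekly), 7, 1 - config$gps_day_missing_prob)
    observed <- sim$weekly |>
      dplyr::select(
        "participant_id", "week_index", "week_start",
        "mean_homestay", "mean_entropy", "mean_distance"
      ) |>
      dplyr::mutate(
        n_gps_days = n_gps_days,
        dplyr::across(
          c("mean_homestay", "mean_entropy", "mean_distance"),
          ~ ifelse(n_gps_days < 3, NA_real_, .x)
        )
      ) |>
      decompose_weekly() |>
      dplyr::left_join(
        dplyr::select(sim$weekly, "participant_id", "week_index",
          "event_flag", "responded", "ideation_flag"),
        by = c("participant_id", "week_index")
      )
    list(
      decomposed = observed,
      panel = build_panel(observed, lag = lag, outcome = "event"),
      events = sim$events,
      esm = sim$esm,
      ground_truth = sim$ground_truth
    )
  })
}
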