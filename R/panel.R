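# Wednesday-aligned weekly panels: aggregation of daily features, the
# <3-GPS-day exclusion rule, event merging, ideation flagging, the
# within-/between-person decomposition, and lagged panel assembly.

EVENT_TYPES <- c(
  "actual_attempt", "aborted_attempt", "interrupted_attempt",
  "ed_visit", "hospitalization"
)
ATTEMPT_TYPES <- c("actual_attempt", "aborted_attempt", "interrupted_attempt")

# Most recent Wednesday on or before `date`.
floor_wednesday <- function(date) {
  lubridate::floor_date(date, unit = "week", week_start = 3)
}

#' Aggregate daily mobility features into Wednesday-aligned weeks
#'
#' Weeks run Wednesday 00:00 to Tuesday 24:00 local. Weekly values are the
#' arithmetic means of the available daily values; weeks with fewer than 3
#' GPS days keep their row for bookkeeping but have the features marked
#' missing. The week grid is completed from each participant's enrollment
#' week through their last observed week (or `n_weeks` when supplied), so
#' lag alignment sees every calendar week.
#'
#' @param daily Output of [daily_features()].
#' @param enrollment Tibble: `participant_id`, `enrollment_date`.
#' @param n_weeks Optional study length in weeks; daily rows outside the
#'   window are dropped with a warning.
#' @param min_gps_days Exclusion threshold (default 3).
#' @return Tibble: `participant_id`, `week_index`, `week_start`,
#'   `mean_homestay`, `mean_entropy`, `mean_distance`, `n_gps_days`.
#' @export
aggregate_weekly <- function(daily, enrollment, n_weeks = NULL, min_gps_days = 3) {
  enr <- enrollment |>
    dplyr::mutate(week0 = floor_wednesday(.data$enrollment_date)) |>
    dplyr::select("participant_id", "week0")
  df <- daily |>
    dplyr::inner_join(enr, by = "participant_id") |>
    dplyr::mutate(
      week_start = floor_wednesday(.data$date),
      week_index = as.integer((.data$week_start - .data$week0) / 7)
    )
  out_of_window <- df$week_index < 0 |
    (!is.null(n_weeks) & df$week_index >= (n_weeks %||% Inf))
  if (any(out_of_window)) {
    warning(sprintf("%d daily rows outside the study window dropped",
      sum(out_of_window)), call. = FALSE)
    df <- df[!out_of_window, , drop = FALSE]
  }
  wk <- df |>
    dplyr::group_by(.data$participant_id, .data$week_index, .data$week0) |>
    dplyr::summarise(
      mean_homestay = mean(.data$homestay_h, na.rm = TRUE),
      mean_entropy = mean(.data$entropy_nats, na.rm = TRUE),
      mean_distance = mean(.data$distance_km, na.rm = TRUE),
      n_gps_days = dplyr::n_distinct(.data$date),
      .groups = "drop"
    )
  # complete the week grid per participant
  grid <- wk |>
    dplyr::group_by(.data$participant_id, .data$week0) |>
    dplyr::reframe(week_index = seq(0L, max(
      .data$week_index,
      if (!is.null(n_weeks)) n_weeks - 1L else 0L
    )))
  grid |>
    dplyr::left_join(wk, by = c("participant_id", "week0", "week_index")) |>
    dplyr::mutate(
      n_gps_days = dplyr::coalesce(.data$n_gps_days, 0L),
      week_start = .data$week0 + 7 * .data$week_index,
      dplyr::across(
        c("mean_homestay", "mean_entropy", "mean_distance"),
        ~ ifelse(.env$min_gps_days > 0 & n_gps_days < .env$min_gps_days,
          NA_real_, .x
        )
      )
    ) |>
    dplyr::select(
      "participant_id", "week_index", "week_start",
      "mean_homestay", "mean_entropy", "mean_distance", "n_gps_days"
    ) |>
    dplyr::arrange(.data$participant_id, .data$week_index)
}

#' Merge emergency-department visits and hospitalizations into attempts
#'
#' An ED visit or hospitalization occurring within 7 days after a suicide
#' attempt by the same participant is counted as the same suicidal event
#' as that attempt; the merged event keeps the attempt's date. Attempts
#' never merge with each other, and the operation is idempotent.
#'
#' @param events Tibble: `participant_id`, `event_date` (Date),
#'   `event_type` (actual_attempt, aborted_attempt, interrupted_attempt,
#'   ed_visit, or hospitalization).
#' @return Tibble of merged events: `participant_id`, `event_date`,
#'   `event_type` (of the anchoring record), `n_merged`.
#' @export
merge_events <- function(events) {
  if (nrow(events) == 0) {
    return(tibble::tibble(
      participant_id = character(), event_date = as.Date(character()),
      event_type = character(), n_merged = integer()
    ))
  }
  bad <- setdiff(unique(events$event_type), EVENT_TYPES)
  if (length(bad) > 0) {
    stop("unknown event_type: ", paste(bad, collapse = ", "),
      "; allowed: ", paste(EVENT_TYPES, collapse = ", "),
      call. = FALSE
    )
  }
  events |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::group_map(function(df, key) {
      df <- dplyr::arrange(df, .data$event_date)
      is_att <- df$event_type %in% ATTEMPT_TYPES
      att_dates <- df$event_date[is_att]
      absorbed <- logical(nrow(df))
      parent <- rep(NA_integer_, nrow(df))
      for (i in which(!is_att)) {
        win <- which(att_dates <= df$event_date[i] &
          att_dates >= df$event_date[i] - 7)
        if (length(win) > 0) {
          absorbed[i] <- TRUE
          parent[i] <- which(is_att)[win[length(win)]] # nearest prior attempt
        }
      }
      n_merged <- 1L + tabulate(parent[absorbed], nbins = nrow(df))
      tibble::tibble(
        participant_id = key$participant_id,
        event_date = df$event_date[!absorbed],
        event_type = df$event_type[!absorbed],
        n_merged = n_merged[!absorbed]
      )
    }) |>
    dplyr::bind_rows()
}

#' Flag clinically meaningful suicidal ideation on weekly surveys
#'
#' A responded survey is flagged 1 when the past-week ideation frequency
#' is >= 4 (on the 1-5 scale) or a suicide plan is endorsed; 0 when
#' responded and neither; `NA` when the survey was not answered.
#'
#' @param esm Tibble: `responded` (0/1), `ideation_1to5`, `plan_yn`
#'   (`"yes"`/`"no"` or logical).
#' @return Integer vector (1/0/NA), one per row.
#' @export
flag_ideation <- function(esm) {
  resp <- as.logical(esm$responded)
  idea <- esm$ideation_1to5
  ok <- is.na(idea) | (idea >= 1 & idea <= 5 & idea == round(idea))
  if (any(!ok)) {
    stop("ideation_1to5 outside 1-5 at row(s): ",
      paste(head(which(!ok), 5), collapse = ", "),
      call. = FALSE
    )
  }
  plan <- if (is.character(esm$plan_yn)) esm$plan_yn == "yes" else as.logical(esm$plan_yn)
  out <- ifelse(resp, as.integer(idea >= 4 | plan), NA_integer_)
  as.integer(out)
}

#' Within-/between-person decomposition of weekly features
#'
#' Splits each weekly feature into a participant-mean-centered term,
#' z-scored by the pooled SD of all centered values, and a participant-mean
#' term, z-scored by the SD of person means across participants. The
#' within term then measures weekly change from one's own mean in SD
#' units; the between term measures stable differences between
#' participants. Participants with fewer than 2 feature-bearing weeks get
#' missing within terms (`flag_few_weeks`).
#'
#' @param weekly Output of [aggregate_weekly()].
#' @return `weekly` with added columns `hw_within`, `en_within`,
#'   `di_within`, `hw_between`, `en_between`, `di_between`,
#'   `flag_few_weeks`, plus attribute `"scaling"` recording the centers and
#'   SDs used.
#' @export
decompose_weekly <- function(weekly) {
  feats <- c(
    hw = "mean_homestay", en = "mean_entropy", di = "mean_distance"
  )
  out <- weekly
  scaling <- list()
  for (k in names(feats)) {
    x <- weekly[[feats[[k]]]]
    pid <- weekly$participant_id
    pm <- tapply(x, pid, mean, na.rm = TRUE)
    n_usable <- tapply(!is.na(x), pid, sum)
    pm[n_usable == 0] <- NA
    person_mean <- as.numeric(pm[as.character(pid)])
    centered <- x - person_mean
    few <- as.numeric(n_usable[as.character(pid)]) < 2
    centered[few] <- NA
    sd_within <- sd(centered, na.rm = TRUE)
    pm_ok <- pm[!is.na(pm)]
    grand <- mean(pm_ok)
    sd_between <- sd(pm_ok)
    out[[paste0(k, "_within")]] <- centered / sd_within
    out[[paste0(k, "_between")]] <- (person_mean - grand) / sd_between
    scaling[[k]] <- list(
      grand_person_mean = grand, sd_within = sd_within, sd_between = sd_between,
      person_means = pm
    )
    if (k == names(feats)[1]) out$flag_few_weeks <- few
  }
  attr(out, "scaling") <- scaling
  out
}

#' Weekly outcome table from surveys and events
#'
#' Maps merged events and weekly surveys onto the Wednesday-aligned week
#' grid. A week's `event_flag` is 1 when at least one merged event is
#' dated inside it. A survey delivered the following Wednesday reports on
#' this week, so a survey dated `d` is assigned to the week containing
#' `d - 1`.
#'
#' @param weekly Week grid (from [aggregate_weekly()]).
#' @param esm Survey tibble: `participant_id`, `survey_date`, `responded`,
#'   `ideation_1to5`, `plan_yn`.
#' @param events Raw event tibble (merged internally via [merge_events()]).
#' @return `weekly` plus `event_flag`, `responded`, `ideation_flag`.
#' @export
outcome_weeks <- function(weekly, esm, events) {
  merged <- merge_events(events)
  ev <- merged |>
    dplyr::mutate(week_start = floor_wednesday(.data$event_date)) |>
    dplyr::count(.data$participant_id, .data$week_start, name = "n_events")
  esm2 <- esm |>
    dplyr::mutate(
      week_start = floor_wednesday(.data$survey_date - 1),
      ideation_flag = flag_ideation(esm)
    ) |>
    dplyr::group_by(.data$participant_id, .data$week_start) |>
    dplyr::summarise(
      responded = as.integer(any(as.logical(.data$responded))),
      ideation_flag = if (any(!is.na(.data$ideation_flag))) {
        max(.data$ideation_flag, na.rm = TRUE)
      } else NA_integer_,
      .groups = "drop"
    )
  weekly |>
    dplyr::left_join(ev, by = c("participant_id", "week_start")) |>
    dplyr::left_join(esm2, by = c("participant_id", "week_start")) |>
    dplyr::mutate(
      event_flag = as.integer(dplyr::coalesce(.data$n_events, 0L) > 0),
      responded = dplyr::coalesce(.data$responded, 0L)
    ) |>
    dplyr::select(-"n_events")
}

#' Assemble the lagged analysis panel
#'
#' Pairs the outcome in week T with the within-person feature terms from
#' week T - lag (between-person terms are constant within participant).
#' Rows lacking the lagged features are dropped; for the ideation outcome,
#' weeks without a survey response are dropped too. `weeks_since_baseline`
#' is the outcome week index.
#'
#' @param decomposed Output of [decompose_weekly()] joined with
#'   [outcome_weeks()] columns (`event_flag`, `responded`, `ideation_flag`).
#' @param lag Non-negative feature lag in weeks (default 1: prior-week
#'   features predict this week's outcome).
#' @param outcome `"event"` or `"ideation"`.
#' @return Panel tibble with `outcome_event`/`outcome_ideation`,
#'   `hw_within`, ..., `di_between`, `weeks_since_baseline`, `lag`.
#' @export
build_panel <- function(decomposed, lag = 1, outcome = c("event", "ideation")) {
  outcome <- match.arg(outcome)
  if (lag < 0) stop("lag must be >= 0", call. = FALSE)
  within_cols <- c("hw_within", "en_within", "di_within")
  between_cols <- c("hw_between", "en_between", "di_between")
  lagged <- decomposed |>
    dplyr::select("participant_id", "week_index", dplyr::all_of(within_cols)) |>
    dplyr::mutate(week_index = .data$week_index + lag)
  panel <- decomposed |>
    dplyr::select(
      "participant_id", "week_index", "week_start",
      dplyr::all_of(between_cols),
      "event_flag", "responded", "ideation_flag"
    ) |>
    dplyr::inner_join(lagged, by = c("participant_id", "week_index")) |>
    dplyr::filter(!is.na(.data$hw_within), !is.na(.data$en_within),
      !is.na(.data$di_within), !is.na(.data$hw_between))
  if (outcome == "ideation") {
    panel <- panel |>
      dplyr::filter(.data$responded == 1, !is.na(.data$ideation_flag)) |>
      dplyr::mutate(outcome_ideation = .data$ideation_flag)
  } else {
    panel <- dplyr::mutate(panel, outcome_event = .data$event_flag)
  }
  panel |>
    dplyr::mutate(weeks_since_baseline = .data$week_index, lag = .env$lag) |>
    dplyr::select(
      "participant_id", "week_index", "week_start",
      dplyr::any_of(c("outcome_event", "outcome_ideation")),
      dplyr::all_of(c(within_cols, between_cols)),
      "weeks_since_baseline", "lag"
    )
}

#' Reversed-direction panel: does an event predict next week's mobility?
#'
#' Pairs the event indicator at week T - 1 with a within-person feature
#' term at week T as a Gaussian outcome, for the bidirectional check.
#'
#' @param decomposed As for [build_panel()].
#' @param feature One of `"hw_within"`, `"en_within"`, `"di_within"`.
#' @return Tibble: `participant_id`, `week_index`, `feature_value`,
#'   `event_prev`, `weeks_since_baseline`.
#' @export
build_reversed_panel <- function(decomposed,
                                 feature = c("hw_within", "en_within", "di_within")) {
  feature <- match.arg(feature)
  prev <- decomposed |>
    dplyr::select("participant_id", "week_index", "event_flag") |>
    dplyr::mutate(week_index = .data$week_index + 1) |>
    dplyr::rename(event_prev = "event_flag")
  decomposed |>
    dplyr::select("participant_id", "week_index",
      feature_value = dplyr::all_of(feature)
    ) |>
    dplyr::inner_join(prev, by = c("participant_id", "week_index")) |>
    dplyr::filter(!is.na(.data$feature_value), !is.na(.data$event_prev)) |>
    dplyr::mutate(weeks_since_baseline = .data$week_index)
}
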