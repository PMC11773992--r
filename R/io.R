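# Schema-validating CSV readers and the cohort writer. All interchange is
# plain CSV with fixed column schemas; validation failures are collected
# and reported together with row numbers.

stop_validation <- function(file, problems) {
  if (length(problems) > 0) {
    stop(sprintf(
      "validation of %s failed:\n%s", file,
      paste("  -", problems, collapse = "\n")
    ), call. = FALSE)
  }
}

require_cols <- function(df, cols, file) {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0) {
    stop(sprintf("%s: missing column(s) %s", file, paste(miss, collapse = ", ")),
      call. = FALSE)
  }
}

#' Read and validate a GPS fix CSV
#'
#' Schema: `participant_id,timestamp,lat_deg,lon_deg,accuracy_m` with
#' ISO-8601 local timestamps. Checks coordinate bounds, timestamp
#' parseability and strict within-participant time ordering; all row-level
#' problems are reported together.
#'
#' @param path CSV path.
#' @return Tibble: `participant_id`, `timestamp` (POSIXct, UTC), `lat`,
#'   `lon`, `accuracy_m`.
#' @export
read_gps_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  require_cols(df, c("participant_id", "timestamp", "lat_deg", "lon_deg"), path)
  probs <- character()
  ts <- as.POSIXct(df$timestamp, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  bad_ts <- which(is.na(ts) & !is.na(df$timestamp))
  if (length(bad_ts) > 0) {
    probs <- c(probs, sprintf("unparseable timestamp at row(s) %s",
      paste(head(bad_ts, 5), collapse = ", ")))
  }
  bad_lat <- which(!is.finite(df$lat_deg) | abs(df$lat_deg) > 90)
  if (length(bad_lat) > 0) {
    probs <- c(probs, sprintf("latitude outside [-90,90] at row(s) %s",
      paste(head(bad_lat, 5), collapse = ", ")))
  }
  bad_lon <- which(!is.finite(df$lon_deg) | abs(df$lon_deg) > 180)
  if (length(bad_lon) > 0) {
    probs <- c(probs, sprintf("longitude outside [-180,180] at row(s) %s",
      paste(head(bad_lon, 5), collapse = ", ")))
  }
  if (length(probs) == 0) {
    ord <- tapply(as.numeric(ts), df$participant_id, function(x) all(diff(x) > 0))
    if (any(!ord)) {
      probs <- c(probs, sprintf(
        "timestamps not strictly increasing for participant(s) %s",
        paste(names(ord)[!ord], collapse = ", ")
      ))
    }
  }
  stop_validation(path, probs)
  tibble::tibble(
    participant_id = as.character(df$participant_id),
    timestamp = ts, lat = df$lat_deg, lon = df$lon_deg,
    accuracy_m = if ("accuracy_m" %in% names(df)) df$accuracy_m else NA_real_
  )
}

#' Read and validate a weekly survey CSV
#'
#' Schema: `participant_id,survey_date,responded,ideation_1to5,plan_yn,attempt_yn`.
#' Responded rows must have ideation in 1-5 and plan in yes/no.
#'
#' @param path CSV path.
#' @return Tibble with parsed dates.
#' @export
read_esm_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  require_cols(df, c("participant_id", "survey_date", "responded",
    "ideation_1to5", "plan_yn"), path)
  probs <- character()
  dt <- as.Date(df$survey_date)
  if (anyNA(dt) && !all(is.na(df$survey_date[is.na(dt)]))) {
    probs <- c(probs, sprintf("unparseable survey_date at row(s) %s",
      paste(head(which(is.na(dt)), 5), collapse = ", ")))
  }
  resp <- df$responded %in% c(0, 1)
  if (any(!resp)) {
    probs <- c(probs, sprintf("responded not 0/1 at row(s) %s",
      paste(head(which(!resp), 5), collapse = ", ")))
  }
  idea <- df$ideation_1to5
  bad_idea <- which(df$responded == 1 &
    (is.na(idea) | idea < 1 | idea > 5 | idea != round(idea)))
  if (length(bad_idea) > 0) {
    probs <- c(probs, sprintf("ideation_1to5 outside 1-5 at row(s) %s",
      paste(head(bad_idea, 5), collapse = ", ")))
  }
  bad_plan <- which(df$responded == 1 & !(df$plan_yn %in% c("yes", "no")))
  if (length(bad_plan) > 0) {
    probs <- c(probs, sprintf("plan_yn not yes/no at row(s) %s",
      paste(head(bad_plan, 5), collapse = ", ")))
  }
  stop_validation(path, probs)
  tibble::tibble(
    participant_id = as.character(df$participant_id),
    survey_date = dt, responded = as.integer(df$responded),
    ideation_1to5 = as.integer(idea), plan_yn = df$plan_yn,
    attempt_yn = if ("attempt_yn" %in% names(df)) df$attempt_yn else NA_character_
  )
}

#' Read and validate a suicidal-event CSV
#'
#' Schema: `participant_id,event_date,event_type`, with event types among
#' actual_attempt, aborted_attempt, interrupted_attempt, ed_visit,
#' hospitalization.
#'
#' @param path CSV path.
#' @return Tibble with parsed dates.
#' @export
read_events_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  require_cols(df, c("participant_id", "event_date", "event_type"), path)
  probs <- character()
  dt <- as.Date(df$event_date)
  if (anyNA(dt)) {
    probs <- c(probs, sprintf("unparseable event_date at row(s) %s",
      paste(head(which(is.na(dt)), 5), collapse = ", ")))
  }
  bad_type <- which(!(df$event_type %in% EVENT_TYPES))
  if (length(bad_type) > 0) {
    probs <- c(probs, sprintf(
      "unknown event_type at row(s) %s (allowed: %s)",
      paste(head(bad_type, 5), collapse = ", "),
      paste(EVENT_TYPES, collapse = ", ")
    ))
  }
  stop_validation(path, probs)
  tibble::tibble(
    participant_id = as.character(df$participant_id),
    event_date = dt, event_type = df$event_type
  )
}

#' Read and validate a baseline covariate CSV
#'
#' Schema: `participant_id,ssi,site,sex,age,device,enrollment_date`.
#'
#' @param path CSV path.
#' @return Tibble with parsed dates.
#' @export
read_baseline_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  require_cols(df, c("participant_id", "ssi", "site", "sex", "age", "device",
    "enrollment_date"), path)
  probs <- character()
  dt <- as.Date(df$enrollment_date)
  if (anyNA(dt)) {
    probs <- c(probs, sprintf("unparseable enrollment_date at row(s) %s",
      paste(head(which(is.na(dt)), 5), collapse = ", ")))
  }
  if (any(duplicated(df$participant_id))) {
    probs <- c(probs, "duplicate participant_id")
  }
  stop_validation(path, probs)
  tibble::tibble(
    participant_id = as.character(df$participant_id),
    ssi = df$ssi, site = df$site, sex = df$sex, age = df$age,
    device = df$device, enrollment_date = dt
  )
}

#' Write a synthetic cohort to CSV + JSON
#'
#' Writes `gps.csv`, `esm.csv`, `events.csv`, `baseline.csv` and
#' `ground_truth.json` with fixed numeric formatting so that a fixed seed
#' produces byte-identical files and the tables round-trip through the
#' `read_*_csv()` readers.
#'
#' @param cohort Output of [simulate_cohort()].
#' @param dir Target directory (created if needed).
#' @param overwrite Refuse to overwrite existing files unless TRUE.
#' @return Invisibly, the written file paths.
#' @export
write_cohort <- function(cohort, dir, overwrite = FALSE) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("gps.csv", "esm.csv", "events.csv",
    "baseline.csv", "ground_truth.json"))
  if (!overwrite && any(file.exists(paths))) {
    stop("output files exist; use overwrite = TRUE", call. = FALSE)
  }
  gps <- data.frame(
    participant_id = cohort$gps$participant_id,
    timestamp = format(cohort$gps$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
    lat_deg = sprintf("%.8f", cohort$gps$lat),
    lon_deg = sprintf("%.8f", cohort$gps$lon),
    accuracy_m = sprintf("%.1f", cohort$gps$accuracy_m)
  )
  utils::write.csv(gps, paths[1], row.names = FALSE, quote = FALSE)
  utils::write.csv(as.data.frame(cohort$esm), paths[2], row.names = FALSE)
  utils::write.csv(as.data.frame(cohort$events), paths[3], row.names = FALSE)
  utils::write.csv(as.data.frame(cohort$baseline), paths[4], row.names = FALSE)
  gt <- cohort$ground_truth
  jsonlite::write_json(list(
    true_beta = as.list(gt$true_beta),
    true_sigma_u = gt$true_sigma_u,
    marginal_event_rate = gt$marginal_event_rate,
    homes = purrr::imap(gt$homes, ~ list(lat = .x[["lat"]], lon = .x[["lon"]]))
  ), paths[5], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}
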