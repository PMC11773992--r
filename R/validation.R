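# Predictive-accuracy machinery: Mann-Whitney AUC, the five-model card
# suite, within-person leave-future-out weekly prediction, and
# between-person first-month identification.

#' Area under the ROC curve (Mann-Whitney with midranks)
#'
#' AUC = U / (n_pos * n_neg) where U is the Mann-Whitney statistic of the
#' positive-class scores with midrank tie handling; identical to
#' trapezoidal ROC integration. Constant scores give exactly 0.5.
#'
#' @param scores Numeric risk scores (higher = more positive).
#' @param labels Binary labels (0/1 or logical).
#' @return AUC in `[0, 1]`.
#' @export
auc_mw <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]
  labels <- labels[ok]
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("AUC undefined: single-class labels", call. = FALSE)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' The five validation model cards
#'
#' 1 all-geo, 2 homestay-only, 3 baseline-only (SSI, site, sex, age,
#' device type), 4 homestay + baseline, 5 all-geo + baseline.
#'
#' @return Tibble: `model_id`, `label`, `features` (list column of term
#'   names).
#' @export
model_cards <- function() {
  geo <- c("hw_within", "en_within", "di_within",
    "hw_between", "en_between", "di_between")
  hs <- c("hw_within", "hw_between")
  base <- c("ssi", "site", "sex", "age", "device")
  tibble::tibble(
    model_id = 1:5,
    label = c("all-geo", "homestay-only", "baseline-only",
      "homestay+baseline", "all-geo+baseline"),
    features = list(geo, hs, base, c(hs, base), c(geo, base))
  )
}

# Percentile bootstrap CI for AUC over resampled test rows.
boot_auc_ci <- function(scores, labels, B, level = 0.95) {
  n <- length(scores)
  stat <- vapply(seq_len(B), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    tryCatch(auc_mw(scores[idx], labels[idx]), error = function(e) NA_real_)
  }, numeric(1))
  stat <- stat[!is.na(stat)]
  a <- (1 - level) / 2
  quantile(stat, c(a, 1 - a), names = FALSE)
}

# Geo model-card features use first-month means for the between-person
# design; for LFO they are panel columns already.
card_formula <- function(outcome, features) {
  as.formula(paste(outcome, "~", paste(features, collapse = " + ")))
}

#' Leave-future-out weekly prediction
#'
#' For each participant, panel weeks are split at the midpoint of that
#' participant's own study span. One random-intercept logistic model per
#' card is fitted on the pooled first halves; held-out second-half weeks
#' are scored with the fixed effects only (no random intercept, so
#' accuracy is not driven by individual outcome histories). Reports
#' Mann-Whitney AUC per card with a percentile bootstrap CI over resampled
#' test rows.
#'
#' @param panel A lagged panel from [build_panel()].
#' @param baseline Baseline covariate tibble (`participant_id`, `ssi`,
#'   `site`, `sex`, `age`, `device`).
#' @param cards Model cards (default all five from [model_cards()]).
#' @param boot Bootstrap resamples (default 2000).
#' @param seed Seed for the bootstrap.
#' @param use_glmm Fit training models with the random intercept (default
#'   TRUE); FALSE falls back to plain logistic regression (useful in
#'   large simulation sweeps).
#' @return Tibble of validation results: `model_id`, `label`, `design`,
#'   `outcome`, `auc`, `ci_low`, `ci_high`, `n_test`, `n_pos`,
#'   `above_chance` (lower CI bound >= 0.5), `note`.
#' @export
leave_future_out <- function(panel, baseline, cards = model_cards(),
                             boot = 2000, seed = 1, use_glmm = TRUE) {
  outcome <- intersect(c("outcome_event", "outcome_ideation"), names(panel))[1]
  if (is.na(outcome)) stop("panel lacks an outcome column", call. = FALSE)
  df <- dplyr::inner_join(panel, baseline, by = "participant_id") |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::mutate(
      .mid = (min(.data$week_index) + max(.data$week_index)) / 2,
      .test = .data$week_index > .data$.mid
    ) |>
    dplyr::ungroup()
  train <- dplyr::filter(df, !.data$.test)
  test <- dplyr::filter(df, .data$.test)

  outcome_label <- sub("outcome_", "", outcome)
  n_pos_test <- sum(test[[outcome]] == 1)
  with_local_seed(seed, {
    purrr::pmap(cards, function(model_id, label, features) {
      out <- tibble::tibble(
        model_id = model_id, label = label, design = "leave-future-out",
        outcome = outcome_label,
        auc = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
        n_test = nrow(test), n_pos = n_pos_test,
        above_chance = NA, note = ""
      )
      if (sum(train[[outcome]]) == 0 || out$n_pos == 0) {
        out$note <- "undefined: no positives in a split"
        return(out)
      }
      f <- card_formula(outcome, features)
      scores <- tryCatch({
        if (use_glmm) {
          fit <- fit_glmm(train, f)
          predict(fit, test, type = "link")
        } else {
          fit <- suppressWarnings(glm(f, data = train, family = binomial()))
          predict(fit, newdata = test, type = "link")
        }
      }, error = function(e) NULL)
      if (is.null(scores)) {
        out$note <- "fit failed"
        return(out)
      }
      out$auc <- auc_mw(scores, test[[outcome]])
      ci <- boot_auc_ci(scores, test[[outcome]], B = boot)
      out$ci_low <- ci[1]
      out$ci_high <- ci[2]
      out$above_chance <- ci[1] >= 0.5
      out
    }) |>
      dplyr::bind_rows()
  })
}

#' First-month feature aggregates per participant
#'
#' Mean of each daily feature over the first `window_days` days from
#' enrollment. Participants with fewer than `min_days` observed days in
#' the window are flagged insufficient (features set missing).
#'
#' @param daily Output of [daily_features()].
#' @param enrollment Tibble: `participant_id`, `enrollment_date`.
#' @param window_days Aggregation window (default 28).
#' @param min_days Minimum observed days required (default 12).
#' @return Tibble: `participant_id`, `hw_month1`, `en_month1`,
#'   `di_month1`, `n_days`, `insufficient`.
#' @export
first_month_aggregate <- function(daily, enrollment, window_days = 28,
                                  min_days = 12) {
  daily |>
    dplyr::inner_join(enrollment, by = "participant_id") |>
    dplyr::filter(
      .data$date >= .data$enrollment_date,
      .data$date < .data$enrollment_date + window_days
    ) |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(
      hw_month1 = mean(.data$homestay_h, na.rm = TRUE),
      en_month1 = mean(.data$entropy_nats, na.rm = TRUE),
      di_month1 = mean(.data$distance_km, na.rm = TRUE),
      n_days = dplyr::n_distinct(.data$date),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      insufficient = .data$n_days < min_days,
      dplyr::across(
        c("hw_month1", "en_month1", "di_month1"),
        ~ ifelse(.data$insufficient, NA_real_, .x)
      )
    )
}

#' Between-person identification from first-month aggregates
#'
#' Plain logistic regression (one row per participant, no random
#' intercept) per model card, over repeated random 70/30 train/test
#' participant splits. Splits whose test fold has no positive participant
#' are redrawn and counted. Reported AUC is the mean over repetitions;
#' the CI is the 2.5/97.5 percentile over repetitions.
#'
#' @param subjects One row per participant: outcome column (0/1),
#'   `hw_month1`, `en_month1`, `di_month1`, and baseline covariates.
#' @param outcome Name of the outcome column.
#' @param cards Model cards; geo feature names are mapped to the
#'   first-month aggregates.
#' @param split Training fraction (default 0.7).
#' @param reps Number of repetitions (default 10000).
#' @param seed Master seed; repetition r always sees the same split for a
#'   given master seed regardless of `reps`.
#' @return Tibble of validation results (as [leave_future_out()]), plus
#'   `n_redraws`.
#' @export
between_person <- function(subjects, outcome, cards = model_cards(),
                           split = 0.7, reps = 10000, seed = 1) {
  geo_map <- c(
    hw_within = "hw_month1", en_within = "en_month1", di_within = "di_month1",
    hw_between = NA, en_between = NA, di_between = NA
  )
  subjects <- dplyr::filter(subjects, !is.na(.data$hw_month1))
  n <- nrow(subjects)
  n_pos_total <- sum(subjects[[outcome]] == 1)
  if (n_pos_total < 3) {
    stop("fewer than 3 positive participants; increase the simulated ",
      "effect or cohort size", call. = FALSE)
  }
  n_train <- round(split * n)
  with_local_seed(seed, {
    rep_seeds <- sample.int(.Machine$integer.max, reps)
    purrr::pmap(cards, function(model_id, label, features) {
      feats <- unique(c(
        as.character(na.omit(unname(geo_map[features[features %in% names(geo_map)]]))),
        features[!features %in% names(geo_map)]
      ))
      f <- card_formula(outcome, feats)
      aucs <- numeric(reps)
      redraws <- 0L
      for (r in seq_len(reps)) {
        set.seed(rep_seeds[r])
        repeat {
          idx <- sample.int(n, n_train)
          test <- subjects[-idx, , drop = FALSE]
          if (sum(test[[outcome]] == 1) >= 1 &&
            sum(test[[outcome]] == 0) >= 1 &&
            sum(subjects[[outcome]][idx] == 1) >= 1) break
          redraws <- redraws + 1L
        }
        fit <- suppressWarnings(
          glm(f, data = subjects[idx, , drop = FALSE], family = binomial())
        )
        sc <- suppressWarnings(predict(fit, newdata = test, type = "link"))
        aucs[r] <- auc_mw(sc, test[[outcome]])
      }
      tibble::tibble(
        model_id = model_id, label = label, design = "between-person",
        outcome = outcome,
        auc = mean(aucs),
        ci_low = quantile(aucs, 0.025, names = FALSE),
        ci_high = quantile(aucs, 0.975, names = FALSE),
        n_test = n - n_train, n_pos = n_pos_total,
        above_chance = quantile(aucs, 0.025, names = FALSE) >= 0.5,
        note = "", n_redraws = redraws
      )
    }) |>
      dplyr::bind_rows()
  })
}
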