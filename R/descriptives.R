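# Cohort-comparison statistics (site-by-characteristic tables): odds
# ratios, chi-square tests, Welch t tests, Cohen's d, Cramer's V, plus
# panel bookkeeping counts.

#' Odds ratio from a 2x2 contingency table
#'
#' `tbl` rows are characteristic present/absent, columns are the two
#' groups; the OR is the odds in the second column over the odds in the
#' first, `(a22/a12) / (a21/a11)` with rows (present, absent). A zero cell
#' triggers the Haldane-Anscombe 0.5 correction, flagged in the output.
#'
#' @param tbl 2x2 matrix of counts: rows = characteristic (yes, no),
#'   columns = groups (reference first).
#' @return Tibble: `or`, `log_or`, `se_log_or`, `corrected`.
#' @export
odds_ratio_2x2 <- function(tbl) {
  stopifnot(is.matrix(tbl), all(dim(tbl) == 2), all(tbl >= 0))
  corrected <- any(tbl == 0)
  t2 <- tbl + if (corrected) 0.5 else 0
  or <- (t2[1, 2] * t2[2, 1]) / (t2[2, 2] * t2[1, 1])
  tibble::tibble(
    or = or,
    log_or = log(or),
    se_log_or = sqrt(sum(1 / t2)),
    corrected = corrected
  )
}

#' Pearson chi-square test for an r x c table
#'
#' 2x2 tables use the Yates continuity correction; larger tables use the
#' uncorrected Pearson statistic (matching how site-comparison tables are
#' conventionally reported). `correct` overrides the default.
#'
#' @param tbl Matrix of counts, at least 2x2.
#' @param correct Continuity correction; default `NULL` = Yates iff 2x2.
#' @return Tibble: `statistic`, `df`, `p.value`, `corrected`,
#'   `min_expected`, `small_expected` (any expected cell < 1).
#' @export
chi_square <- function(tbl, correct = NULL) {
  stopifnot(is.matrix(tbl), nrow(tbl) >= 2, ncol(tbl) >= 2, all(tbl >= 0))
  if (is.null(correct)) correct <- all(dim(tbl) == 2)
  ct <- suppressWarnings(stats::chisq.test(tbl, correct = correct))
  min_exp <- min(ct$expected)
  if (min_exp < 1) {
    warning("expected cell count below 1; chi-square approximation is poor",
      call. = FALSE)
  }
  tibble::tibble(
    statistic = unname(ct$statistic),
    df = unname(ct$parameter),
    p.value = ct$p.value,
    corrected = correct,
    min_expected = min_exp,
    small_expected = min_exp < 1
  )
}

#' Welch two-sample t test from group summaries
#'
#' t = (m2 - m1) / sqrt(s1^2/n1 + s2^2/n2) with Welch-Satterthwaite
#' degrees of freedom; the sign convention is second group minus first.
#'
#' @param n1,m1,s1 First (reference) group size, mean, SD.
#' @param n2,m2,s2 Second group size, mean, SD.
#' @param pooled Use the pooled-variance (Student) form instead (default
#'   FALSE).
#' @return Tibble: `t`, `df`, `p.value`, `pooled`.
#' @export
welch_t <- function(n1, m1, s1, n2, m2, s2, pooled = FALSE) {
  stopifnot(n1 >= 2, n2 >= 2, s1 >= 0, s2 >= 0)
  if (s1 == 0 && s2 == 0) stop("zero variance in both groups", call. = FALSE)
  if (pooled) {
    sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2)
    t <- (m2 - m1) / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    v1 <- s1^2 / n1
    v2 <- s2^2 / n2
    t <- (m2 - m1) / sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  }
  tibble::tibble(t = t, df = df, p.value = 2 * pt(-abs(t), df), pooled = pooled)
}

#' Cohen's d from group summaries
#'
#' (m2 - m1) / pooled SD, second group minus first.
#'
#' @inheritParams welch_t
#' @return Scalar d.
#' @export
cohens_d <- function(n1, m1, s1, n2, m2, s2) {
  sp <- sqrt(((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2))
  (m2 - m1) / sp
}

#' Cramer's V in both reporting conventions
#'
#' The standard convention divides the (uncorrected) chi-square by
#' `n * min(r-1, c-1)`; a df-normalized variant divides by
#' `n * (r-1)(c-1)`. Both are returned because published tables are not
#' always explicit about which was used (they coincide for 2x2 tables).
#'
#' @param tbl Matrix of counts.
#' @return Tibble: `v_standard`, `v_df_normalized`, `statistic`, `n`.
#' @export
cramers_v <- function(tbl) {
  ct <- suppressWarnings(stats::chisq.test(tbl, correct = FALSE))
  n <- sum(tbl)
  chi2 <- unname(ct$statistic)
  r <- nrow(tbl)
  c <- ncol(tbl)
  tibble::tibble(
    v_standard = sqrt(chi2 / (n * min(r - 1, c - 1))),
    v_df_normalized = sqrt(chi2 / (n * (r - 1) * (c - 1))),
    statistic = chi2,
    n = n
  )
}

#' Panel bookkeeping counts
#'
#' Audit counts after a pipeline run: usable event-weeks and
#' ideation-weeks in the lag-1 panels, merged event count and unique
#' event participants, and the GPS-day availability fraction.
#'
#' @param event_panel,ideation_panel Panels from [build_panel()].
#' @param events Raw event table (merged internally).
#' @param daily Daily features table.
#' @param enrollment Tibble with `participant_id`, `enrollment_date`.
#' @param n_weeks Study length in weeks (for the availability denominator).
#' @return One-row tibble of counts.
#' @export
panel_counts <- function(event_panel, ideation_panel, events, daily,
                         enrollment, n_weeks) {
  merged <- merge_events(events)
  tibble::tibble(
    event_weeks = nrow(event_panel),
    ideation_weeks = nrow(ideation_panel),
    n_raw_events = nrow(events),
    n_merged_events = nrow(merged),
    n_event_participants = dplyr::n_distinct(merged$participant_id),
    gps_day_fraction = nrow(daily) /
      (dplyr::n_distinct(enrollment$participant_id) * n_weeks * 7)
  )
}

#' Site-comparison summary for a categorical characteristic
#'
#' Convenience wrapper reproducing one row of a two-site comparison
#' table: Yates chi-square (2x2), odds ratio oriented second site over
#' first, and Cramer's V for larger tables.
#'
#' @param tbl Matrix of counts, rows = characteristic levels, columns =
#'   sites (reference first).
#' @return Tibble combining [chi_square()] with the effect size.
#' @export
site_comparison <- function(tbl) {
  cs <- chi_square(tbl)
  if (all(dim(tbl) == 2)) {
    dplyr::bind_cols(cs, dplyr::select(odds_ratio_2x2(tbl), "or", "corrected2x2" = "corrected"))
  } else {
    dplyr::bind_cols(cs, dplyr::select(cramers_v(tbl), "v_standard", "v_df_normalized"))
  }
}
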