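# End-to-end pipeline: simulate -> features -> panel -> fit -> validate ->
# descriptives, with a manifest recording the config hash, seed and
# per-file checksums so deterministic stages can be audited and re-run.

run_stage <- function(name, quiet, code) {
  if (!quiet) message(sprintf("[%s] ...", name))
  tryCatch(force(code), error = function(e) {
    stop(sprintf("pipeline halted at stage '%s': %s", name, conditionMessage(e)),
      call. = FALSE)
  })
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Chains every stage: cohort simulation, daily feature extraction, weekly
#' panel construction (event and ideation), the lag-1 random-intercept
#' logistic fit, leave-future-out validation, and bookkeeping
#' descriptives. All outputs are written under `out_dir` along with
#' `manifest.json` (config hash, seed, md5 checksum per file); rerunning
#' with the same config reproduces identical checksums.
#'
#' @param config A [sim_config()]; its `seed` drives every stochastic
#'   stage.
#' @param out_dir Output directory.
#' @param lag Feature lag for the fitted panels (default 1).
#' @param boot Bootstrap resamples for leave-future-out CIs (default 500).
#' @param cards Model cards for validation (default the homestay-only and
#'   baseline-only cards; pass [model_cards()] for all five).
#' @param overwrite Allow overwriting an existing output directory.
#' @param quiet Suppress stage messages.
#' @return Invisibly, a list with the manifest and the in-memory stage
#'   results.
#' @export
run_pipeline <- function(config, out_dir, lag = 1, boot = 500,
                         cards = model_cards()[2:3, ], overwrite = FALSE,
                         quiet = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  cfg_path <- file.path(out_dir, "config.json")
  jsonlite::write_json(unclass(config), cfg_path,
    auto_unbox = TRUE, digits = NA)
  config_hash <- unname(tools::md5sum(cfg_path))

  cohort <- run_stage("simulate", quiet, {
    co <- simulate_cohort(config)
    write_cohort(co, out_dir, overwrite = TRUE)
    co
  })

  daily <- run_stage("features", quiet, {
    d <- daily_features(cohort$gps, radius_m = config$home_radius_m)
    utils::write.csv(
      dplyr::mutate(d, dplyr::across(dplyr::where(is.numeric), ~ round(.x, 6))),
      file.path(out_dir, "daily_features.csv"), row.names = FALSE
    )
    d
  })

  panels <- run_stage("panel", quiet, {
    if (!file.exists(file.path(out_dir, "events.csv"))) {
      stop("events.csv not found")
    }
    enrollment <- dplyr::select(cohort$baseline, "participant_id",
      "enrollment_date")
    weekly <- aggregate_weekly(daily, enrollment, n_weeks = config$n_weeks)
    n_excluded <- sum(weekly$n_gps_days < 3)
    if (!quiet) {
      message(sprintf("  weeks excluded by the <3-GPS-day rule: %d", n_excluded))
      message(sprintf("  merged events: %d", nrow(merge_events(cohort$events))))
    }
    dec <- outcome_weeks(decompose_weekly(weekly), cohort$esm, cohort$events)
    if (!quiet) {
      message(sprintf("  non-response weeks: %d", sum(dec$responded == 0)))
    }
    ev <- build_panel(dec, lag = lag, outcome = "event")
    id <- build_panel(dec, lag = lag, outcome = "ideation")
    utils::write.csv(
      dplyr::mutate(ev, dplyr::across(dplyr::where(is.numeric), ~ round(.x, 6))),
      file.path(out_dir, "weekly_panel.csv"), row.names = FALSE
    )
    list(event = ev, ideation = id, decomposed = dec, weekly = weekly)
  })

  fit <- run_stage("fit", quiet, {
    f <- fit_glmm(
      panels$event,
      outcome_event ~ hw_within + en_within + di_within +
        hw_between + en_between + di_between + weeks_since_baseline
    )
    jsonlite::write_json(list(
      beta = as.list(f$beta), se = as.list(setNames(f$se, names(f$beta))),
      vcov = f$vcov, sigma_u = f$sigma_u, loglik = f$loglik,
      converged = f$converged, penalized = f$penalized,
      n_obs = f$n_obs, n_groups = f$n_groups,
      or_table = report_or(f)
    ), file.path(out_dir, "fit.json"), auto_unbox = TRUE, digits = NA)
    f
  })

  validation <- run_stage("validate", quiet, {
    v <- leave_future_out(panels$event, cohort$baseline, cards = cards,
      boot = boot, seed = config$seed)
    jsonlite::write_json(v, file.path(out_dir, "validation.json"),
      auto_unbox = TRUE, digits = NA)
    v
  })

  descriptives <- run_stage("descriptives", quiet, {
    enrollment <- dplyr::select(cohort$baseline, "participant_id",
      "enrollment_date")
    d <- panel_counts(panels$event, panels$ideation, cohort$events, daily,
      enrollment, config$n_weeks)
    jsonlite::write_json(d, file.path(out_dir, "descriptives.json"),
      auto_unbox = TRUE, digits = NA)
    d
  })

  files <- setdiff(list.files(out_dir), "manifest.json")
  manifest <- list(
    config_hash = config_hash,
    seed = config$seed,
    checksums = as.list(tools::md5sum(file.path(out_dir, sort(files)))) |>
      setNames(sort(files))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(
    manifest = manifest, cohort = cohort, daily = daily, panels = panels,
    fit = fit, validation = validation, descriptives = descriptives
  ))
}
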