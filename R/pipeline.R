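## End-to-end pipeline driver: simulate (or read) a cohort, derive all
## daily tables, feedback and alerts, fit the model battery, and write
## every artifact plus a run manifest.

#' Run the full pipeline
#'
#' Stages: simulate (or load) -> sleep scoring -> HRV -> activity ->
#' symptoms -> feedback -> analysis. All CSV artifacts defined by the
#' module interfaces are written to `out_dir`, together with
#' `manifest.json` (seed, configuration hash, file list); identical
#' config + seed yields identical artifacts and manifest hash.
#'
#' @param config A [sim_config()] (used when `input_dir` is `NULL`).
#' @param out_dir Output directory.
#' @param input_dir Optional directory of cohort CSVs from
#'   [write_cohort()]; when given, data are read instead of simulated
#'   (profiles and surveys are taken as-is and nightly metrics are
#'   derived from the minute stream).
#' @param apply_missing Apply configured day-level missingness after
#'   simulation (ignored for `input_dir` runs).
#' @param skip_week1 Drop the adaptation week in the analysis table.
#' @param nAGQ Quadrature points for the model battery.
#' @param run_battery Fit the 22-model battery (default `TRUE`; skip for
#'   quick smoke runs).
#' @return Invisible list of the main artifacts (`cohort`,
#'   `sleep_nights`, `hrv_daily`, `activity_daily`, `feedback`,
#'   `daily_rows`, `model_results`, `manifest`).
#' @export
run_pipeline <- function(config = sim_config(), out_dir,
                         input_dir = NULL, apply_missing = TRUE,
                         skip_week1 = TRUE, nAGQ = 10,
                         run_battery = TRUE) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  stage <- "simulate"
  res <- tryCatch({
    if (is.null(input_dir)) {
      cohort <- generate_cohort(config)
      if (apply_missing) cohort <- apply_missingness(cohort)
    } else {
      cohort <- read_cohort(input_dir)
      cohort$config <- config
    }
    write_cohort(cohort, out_dir)

    stage <- "sleep"
    sleep_nights <- if (!is.null(cohort$minutes)) {
      score_sleep_nights(cohort$minutes, cohort$profiles,
                         rule1_direction = config$rule1_direction,
                         long_episode_min = config$long_episode_min)
    } else cohort$sleep_nights
    utils::write.csv(sleep_nights, file.path(out_dir, "sleep_nights.csv"),
                     row.names = FALSE, na = "")

    stage <- "hrv"
    hrv_day <- NULL
    if (!is.null(cohort$minutes)) {
      windows <- hrv_windows(cohort$minutes)
      utils::write.csv(windows, file.path(out_dir, "hrv_windows.csv"),
                       row.names = FALSE, na = "")
      hrv_day <- hrv_daily(windows)
      utils::write.csv(hrv_day, file.path(out_dir, "hrv_daily.csv"),
                       row.names = FALSE, na = "")
    }

    stage <- "activity"
    act_day <- NULL
    if (!is.null(cohort$minutes)) {
      act_day <- activity_daily(cohort$minutes)
      utils::write.csv(act_day, file.path(out_dir, "activity_daily.csv"),
                       row.names = FALSE, na = "")
    }

    stage <- "feedback"
    if (!is.null(hrv_day) && !is.null(act_day)) {
      fb <- feedback_cards(hrv_day, sleep_nights, act_day)
      utils::write.csv(fb$cards, file.path(out_dir, "feedback_daily.csv"),
                       row.names = FALSE, na = "")
      alerts <- detect_emergencies(cohort$minutes)
      utils::write.csv(alerts, file.path(out_dir, "alerts.csv"),
                       row.names = FALSE, na = "")
    } else fb <- NULL

    stage <- "analyze"
    rows <- assemble_daily_table(sleep_nights, cohort$surveys,
                                 cohort$profiles, hrv_day = hrv_day,
                                 act_day = act_day, skip_week1 = skip_week1)
    utils::write.csv(rows, file.path(out_dir, "daily_rows.csv"),
                     row.names = FALSE, na = "")
    battery <- NULL
    if (run_battery) {
      battery <- run_model_battery(rows, nAGQ = nAGQ)
      utils::write.csv(battery, file.path(out_dir, "model_results.csv"),
                       row.names = FALSE, na = "")
    }
    list(cohort = cohort, sleep_nights = sleep_nights, hrv_daily = hrv_day,
         activity_daily = act_day, feedback = fb, daily_rows = rows,
         model_results = battery)
  }, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })

  manifest <- list(
    package = "wearlab",
    version = as.character(utils::packageVersion("wearlab")),
    seed = config$seed,
    config_hash = config_hash(config),
    skip_week1 = skip_week1,
    files = sort(list.files(out_dir)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  res$manifest <- manifest
  invisible(res)
}

#' Deterministic hash of a simulation configuration
#'
#' MD5 of the canonical JSON serialization of the config.
#'
#' @param config A [sim_config()].
#' @return Character MD5 hash.
#' @export
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  plain <- lapply(unclass(config), function(v) {
    if (inherits(v, "Date")) format(v, "%Y-%m-%d") else v
  })
  jsonlite::write_json(plain, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

#' Build standard test cohorts
#'
#' `"tiny"` is a 3-participant, 10-day cohort for fast end-to-end
#' checks; `"paper_scale"` is 25 participants with day counts spanning
#' 8-40 days (mean near 32), the dimensions of the study being
#' emulated. Both are generated on demand, deterministically from
#' `seed`.
#'
#' @param size `"tiny"` or `"paper_scale"`.
#' @param seed RNG seed.
#' @param level Generation level, see [sim_config()].
#' @return A `wearlab_cohort`.
#' @export
make_fixtures <- function(size = c("tiny", "paper_scale"), seed = 42L,
                          level = "minute") {
  size <- match.arg(size)
  cfg <- switch(size,
    tiny = sim_config(n_participants = 3L, n_days = 10L, seed = seed,
                      level = level),
    paper_scale = sim_config(
      n_participants = 25L,
      n_days = c(8L, rep(40L, 2L), rep(36L, 5L), rep(33L, 10L),
                 rep(30L, 4L), rep(28L, 3L)),
      seed = seed, level = level))
  generate_cohort(cfg)
}
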