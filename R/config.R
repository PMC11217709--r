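## Simulation configuration.
##
## The generator emulates a six-week living lab of socially vulnerable
## older adults: 25 participants, ~33 days each, a daily chatbot symptom
## survey, and a wrist wearable recording minute-level heart rate,
## sleep/wake classification, steps and activity intensity. Anchored
## quantities (cohort demographics, symptom-day prevalence 0.37,
## within-person sleep-symptom odds ratios, per-domain day-level
## missingness rates) follow the study being emulated; all distributional
## forms for the sensor streams are artifact choices of this package and
## are documented here and in the methods vignette.

#' Simulation configuration for the synthetic living-lab cohort
#'
#' @param n_participants Number of participants (>= 2; study value 25).
#' @param n_days Days of observation per participant (>= 8; study mean
#'   32.28, modal design 33). A vector of length `n_participants` gives
#'   per-person day counts.
#' @param seed Integer RNG seed; identical config + seed gives
#'   byte-identical output.
#' @param beta_sfi True within-person log-odds of a symptomatic day per
#'   unit of person-centered sleep fragmentation on the analysis scale
#'   (awakenings per 100 minutes of sleep, i.e. SFI x 100). Default
#'   `log(2.066)`, the same-day estimate the cohort emulates.
#' @param beta_se True within-person log-odds per percentage point of
#'   person-centered sleep efficiency. Default `log(0.972)`.
#' @param couple_to Which night a day's symptom is coupled to:
#'   `"night_before"` (the night ending that morning; default) or
#'   `"night_after"` (strictly concurrent-evening coupling).
#' @param target_prevalence Marginal proportion of symptomatic days
#'   (default 0.37).
#' @param tau SD of the person-level random intercept on the log-odds
#'   scale (artifact choice, 0.9: moderate between-person heterogeneity).
#' @param b_gds Log-odds per SD of baseline depression score feeding the
#'   person intercept (between-person pathway; yields the expected
#'   positive correlation between baseline depression and the person
#'   mean of daily symptoms).
#' @param b_between_se Log-odds per percentage point of a person's
#'   habitual sleep efficiency (negative: habitually inefficient sleepers
#'   report more symptom days, a between-person pathway only).
#' @param missing_rates Named proportions of participant-days missing per
#'   domain: `survey`, `hrv`, `sleep`, `steps`. Defaults are the study's
#'   printed rates.
#' @param hr_mean,hr_amp,hr_night_dip,hr_noise_sd,hr_ar Circadian heart
#'   rate structure: person mean (bpm), circadian amplitude, extra dip
#'   while asleep, AR(1) noise SD and autocorrelation.
#' @param hr_clamp Length-2 plausibility clamp for generated heart rate.
#'   The default `c(40, 120)` keeps synthetic cohorts free of heart-rate
#'   emergencies (a negative-control property); widen it to inject them.
#' @param tst_mean,tst_person_sd Person-level mean total sleep time
#'   (minutes) and its between-person SD.
#' @param se_mean,se_person_sd Person-level mean sleep efficiency (%) and
#'   its between-person SD.
#' @param wake_mu_meanlog,wake_mu_sdlog Log-normal parameters of the
#'   person-level mean duration (minutes) of a nocturnal wake episode;
#'   with the efficiency target this sets each person's awakening rate.
#' @param frag_night_sdlog Night-to-night log-normal jitter of the wake
#'   volume.
#' @param act_light_mean,act_moderate_mean,act_intense_mean Cohort mean
#'   daily minutes of light / moderate / intense activity.
#' @param act_scale_sdlog Between-person log-normal SD of the activity
#'   volume multiplier.
#' @param n_reversed Number of participants with reversed day/night
#'   cycles (default 1, as observed).
#' @param post_missing_n Participants missing the post-test survey
#'   (default 1, as observed).
#' @param level `"minute"` (full minute streams) or `"day"` (nightly
#'   sleep series and surveys only; the fast path for Monte-Carlo work).
#' @param rule1_direction Rescoring direction for criterion 1, passed to
#'   [rescore_sleep()].
#' @param long_episode_min Passed to [sleep_metrics()].
#' @param start_date First study day.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_participants = 25L,
                       n_days = 33L,
                       seed = 1L,
                       beta_sfi = log(2.066),
                       beta_se = log(0.972),
                       couple_to = c("night_before", "night_after"),
                       target_prevalence = 0.37,
                       tau = 0.9,
                       b_gds = 0.6,
                       b_between_se = -0.06,
                       missing_rates = c(survey = 0.23, hrv = 0.333,
                                         sleep = 0.545, steps = 0.369),
                       hr_mean = 72, hr_amp = 5, hr_night_dip = 7,
                       hr_noise_sd = 2, hr_ar = 0.7,
                       hr_clamp = c(40, 120),
                       tst_mean = 320, tst_person_sd = 80,
                       se_mean = 66, se_person_sd = 10,
                       wake_mu_meanlog = log(18),
                       wake_mu_sdlog = 0.30,
                       frag_night_sdlog = 0.30,
                       act_light_mean = 130, act_moderate_mean = 14,
                       act_intense_mean = 22, act_scale_sdlog = 0.6,
                       n_reversed = 1L,
                       post_missing_n = 1L,
                       level = c("minute", "day"),
                       rule1_direction = c("as_printed", "webster"),
                       long_episode_min = 5L,
                       start_date = as.Date("2023-03-06")) {
  couple_to <- match.arg(couple_to)
  level <- match.arg(level)
  rule1_direction <- match.arg(rule1_direction)
  n_participants <- as.integer(n_participants)
  n_days <- as.integer(n_days)
  if (is.na(n_participants) || n_participants < 2L) {
    stop("n_participants must be an integer >= 2")
  }
  if (length(n_days) == 1L) n_days <- rep(n_days, n_participants)
  if (length(n_days) != n_participants || any(is.na(n_days)) ||
      any(n_days < 8L)) {
    stop("n_days must be >= 8 (per participant)")
  }
  req <- c("survey", "hrv", "sleep", "steps")
  if (!all(req %in% names(missing_rates))) {
    stop("missing_rates needs names: ", paste(req, collapse = ", "))
  }
  extra <- setdiff(names(missing_rates), req)
  if (length(extra)) stop("unknown missingness domain: ", paste(extra, collapse = ", "))
  if (any(missing_rates < 0 | missing_rates > 1)) {
    stop("missing_rates must lie in [0, 1]")
  }
  if (!is.finite(target_prevalence) || target_prevalence <= 0 ||
      target_prevalence >= 1) {
    stop("target_prevalence must lie in (0, 1)")
  }
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}
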