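## Synthetic living-lab cohort generator.
##
## Generation order is fixed so that identical config + seed gives
## byte-identical output: participant profiles, then per participant (in
## id order) nightly sleep series, activity, heart rate, and surveys.
## Nightly series are scored with the package's own sleep-scoring module
## and the day's symptom probability is coupled to the scored metrics of
## the night ending that morning:
##
##   logit p(symptom day d) = alpha_i + beta_sfi * SFIc + beta_se * SEc
##
## where SFIc / SEc are the night's deviations from the person's mean
## over their own generated nights (a person-constant centering; any
## person-constant offset relative to analysis-time centering is
## absorbed by the model's random intercept, which keeps the
## within-person coefficient exactly recoverable).

## Nominal within-person SDs of the centered analysis-scale predictors,
## used only to calibrate the marginal symptom prevalence.
.NOMINAL_SD_SFI100_C <- 1.1
.NOMINAL_SD_SE_C <- 8

#' Generate a synthetic living-lab cohort
#'
#' @param config A [sim_config()].
#' @return List of class `wearlab_cohort`: `profiles`, `surveys`,
#'   `sleep_nights` (the generator's own scoring of its nights),
#'   `minutes` (minute-level records; `NULL` when `config$level ==
#'   "day"`), and `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed, kind = "Mersenne-Twister")
  cfg <- config
  n <- cfg$n_participants
  ids <- sprintf("P%02d", seq_len(n))

  profiles <- .sim_profiles(cfg, ids)
  psleep <- .sim_person_sleep_params(cfg, n)
  pact <- .sim_person_activity_params(cfg, n)
  alpha <- .sim_person_intercepts(cfg, profiles, psleep)

  minutes <- vector("list", n)
  sleep_nights <- vector("list", n)
  surveys <- vector("list", n)

  for (i in seq_len(n)) {
    D <- cfg$n_days[i]
    dates <- cfg$start_date + seq_len(D) - 1L
    rev_cycle <- profiles$reversed_cycle[i]

    nights <- .sim_participant_nights(cfg, psleep[i, ], D)
    sn <- .score_generated_nights(cfg, ids[i], dates, nights, rev_cycle)
    sleep_nights[[i]] <- sn

    if (cfg$level == "minute") {
      grid <- .sim_participant_minutes(cfg, psleep[i, ], pact[i, ], nights,
                                       D, rev_cycle)
      grid$participant_id <- ids[i]
      grid$date <- dates[grid$day]
      minutes[[i]] <- grid[, c("participant_id", "date", "minute",
                               "heart_rate", "sleep_class", "steps",
                               "intensity")]
    }

    surveys[[i]] <- .sim_participant_surveys(cfg, ids[i], dates, sn, alpha[i])
  }

  out <- list(profiles = profiles,
              surveys = do.call(rbind, surveys),
              sleep_nights = do.call(rbind, sleep_nights),
              minutes = if (cfg$level == "minute") do.call(rbind, minutes) else NULL,
              config = cfg)
  rownames(out$surveys) <- NULL
  rownames(out$sleep_nights) <- NULL
  if (!is.null(out$minutes)) rownames(out$minutes) <- NULL
  class(out) <- "wearlab_cohort"
  out
}

## ---- participant-level draws ------------------------------------------

.sim_profiles <- function(cfg, ids) {
  n <- length(ids)
  age <- pmax(65L, round(stats::rnorm(n, 76.4, 4.23)))
  sex <- ifelse(stats::runif(n) < 0.76, "woman", "man")
  education <- sample(1:4, n, replace = TRUE,
                      prob = c(0.56, 0.08, 0.20, 0.16))
  income_band <- sample(1:4, n, replace = TRUE,
                        prob = c(0.16, 0.64, 0.08, 0.12))
  n_chronic <- pmax(0L, round(stats::rnorm(n, 4.2, 1.71)))
  baseline_gds <- pmin(15L, stats::rnbinom(n, size = 2, mu = 4.0))
  baseline_psqi <- pmin(21L, pmax(0L, round(stats::rnorm(n, 8, 2.7))))
  sus_pre <- pmin(100, pmax(0, stats::rnorm(n, 53.3, 24.5)))
  sus_post <- pmin(100, pmax(0, sus_pre + stats::rnorm(n, 6.4, 20)))
  gds_post <- pmin(15L, pmax(0L, baseline_gds + round(stats::rnorm(n, -1, 2.2))))
  psqi_post <- pmin(21L, pmax(0L, baseline_psqi + round(stats::rnorm(n, -1.5, 2.5))))
  reversed <- rep(FALSE, n)
  if (cfg$n_reversed > 0L) {
    reversed[sample.int(n, min(cfg$n_reversed, n))] <- TRUE
  }
  if (cfg$post_missing_n > 0L) {
    drop <- sample.int(n, min(cfg$post_missing_n, n))
    sus_post[drop] <- NA_real_
    gds_post[drop] <- NA_integer_
    psqi_post[drop] <- NA_integer_
  }
  data.frame(participant_id = ids, age = age, sex = sex,
             education = education, income_band = income_band,
             n_chronic = n_chronic, baseline_gds = baseline_gds,
             baseline_psqi = baseline_psqi, sus_pre = sus_pre,
             sus_post = sus_post, gds_post = gds_post,
             psqi_post = psqi_post, reversed_cycle = reversed)
}

.sim_person_sleep_params <- function(cfg, n) {
  tst <- pmin(540, pmax(150, stats::rnorm(n, cfg$tst_mean, cfg$tst_person_sd)))
  se <- pmin(92, pmax(40, stats::rnorm(n, cfg$se_mean, cfg$se_person_sd)))
  tib <- pmin(640, pmax(240, 100 * tst / se))
  # bed time in window minutes (window minute 1 = 18:00); 285 = 22:45
  bed <- pmin(420, pmax(90, stats::rnorm(n, 285, 30)))
  # person mean duration of a nocturnal wake episode (minutes); together
  # with the efficiency target this sets the awakening rate, so habitual
  # fragmentation (count) varies partly independently of efficiency
  wake_mu <- stats::rlnorm(n, cfg$wake_mu_meanlog, cfg$wake_mu_sdlog)
  data.frame(tst_target = tst, se_target = se, tib_target = tib,
             bed_mean = bed, wake_mu = wake_mu)
}

.sim_person_activity_params <- function(cfg, n) {
  scale <- stats::rlnorm(n, -cfg$act_scale_sdlog^2 / 2, cfg$act_scale_sdlog)
  light <- cfg$act_light_mean * scale
  moderate <- cfg$act_moderate_mean * scale
  intense <- cfg$act_intense_mean * scale
  hr_base <- stats::rnorm(n, cfg$hr_mean, 4)
  data.frame(light = light, moderate = moderate, intense = intense,
             hr_base = hr_base)
}

.sim_person_intercepts <- function(cfg, profiles, psleep) {
  v_nom <- cfg$tau^2 + cfg$b_gds^2 +
    (cfg$b_between_se * cfg$se_person_sd)^2 +
    (cfg$beta_sfi * .NOMINAL_SD_SFI100_C)^2 +
    (cfg$beta_se * .NOMINAL_SD_SE_C)^2
  a0 <- stats::qlogis(cfg$target_prevalence) * sqrt(1 + 0.346 * v_nom)
  z_gds <- (profiles$baseline_gds - 4) / 3.5
  a0 + cfg$b_gds * z_gds +
    cfg$b_between_se * (psleep$se_target - cfg$se_mean) +
    cfg$tau * stats::rnorm(nrow(profiles))
}

## ---- nightly sleep series ---------------------------------------------

## One night as a 1080-minute window class vector (1 sleep / 0 wake).
## Awake before bed and after rise; wake episodes scattered inside the
## in-bed span; no uninterrupted sleep run longer than 400 minutes (long
## unbroken sleep is rare in this population and the cap guarantees an
## awake minute inside any long overnight span).
.sim_one_night <- function(cfg, pp) {
  bed <- round(pp$bed_mean + stats::rnorm(1, 0, 25))
  bed <- min(500L, max(31L, bed))
  tib <- round(pp$tib_target * stats::rlnorm(1, 0, 0.10))
  rise <- min(bed + tib, 810L) # never later than 07:30
  tib <- rise - bed
  x <- integer(SLEEP_WINDOW_MIN) # awake
  if (tib < 30L) {
    if (tib > 0L) x[bed:(rise - 1L)] <- 1L
    return(x)
  }
  x[bed:(rise - 1L)] <- 1L
  # nightly wake volume driven by the person's efficiency target; episode
  # count follows from the person's mean episode duration
  wake_frac <- (1 - pp$se_target / 100) * stats::rlnorm(1, 0, cfg$frag_night_sdlog)
  wake_frac <- min(0.55, max(0.02, wake_frac))
  k <- max(1L, stats::rpois(1, wake_frac * tib / pp$wake_mu))
  dur <- 1L + stats::rgeom(k, 1 / pp$wake_mu)
  keep <- cumsum(dur) <= 0.55 * tib
  dur <- dur[keep]
  if (length(dur)) {
    starts <- sample((bed + 10L):(rise - 12L), length(dur), replace = TRUE)
    for (j in seq_along(dur)) {
      seg <- starts[j]:min(starts[j] + dur[j] - 1L, rise - 2L)
      x[seg] <- 0L
    }
  }
  # cap uninterrupted sleep runs at 400 minutes
  repeat {
    r <- rle(x)
    ends <- cumsum(r$lengths)
    long <- which(r$values == 1L & r$lengths > 400L)
    if (!length(long)) break
    for (i in long) {
      mid <- ends[i] - r$lengths[i] %/% 2L
      x[mid:(mid + 1L)] <- 0L
    }
  }
  x
}

.sim_participant_nights <- function(cfg, pp, D) {
  lapply(seq_len(max(D - 1L, 0L)), function(d) .sim_one_night(cfg, pp))
}

.score_generated_nights <- function(cfg, pid, dates, nights, rev_cycle) {
  rows <- lapply(seq_along(nights), function(d) {
    x <- rescore_sleep(nights[[d]], cfg$rule1_direction)
    .sleep_metrics_list(x, long_episode_min = cfg$long_episode_min)
  })
  cols <- names(rows[[1]])
  out <- as.data.frame(lapply(stats::setNames(cols, cols), function(cn) {
    unlist(lapply(rows, `[[`, cn), use.names = FALSE)
  }))
  out <- cbind(data.frame(participant_id = pid,
                          night_date = dates[seq_along(nights)]), out)
  out$onset_time <- window_minute_to_timestamp(out$night_date, out$onset, rev_cycle)
  out$offset_time <- window_minute_to_timestamp(out$night_date, out$offset, rev_cycle)
  out$rule1_direction <- cfg$rule1_direction
  out
}

## ---- daily surveys -----------------------------------------------------

.sim_participant_surveys <- function(cfg, pid, dates, sleep_nights, alpha_i) {
  D <- length(dates)
  valid <- sleep_nights$valid
  sfi100 <- 100 * sleep_nights$sfi
  se <- sleep_nights$se
  m_sfi <- if (any(valid)) mean(sfi100[valid]) else NA_real_
  m_se <- if (any(valid)) mean(se[valid]) else NA_real_

  greet <- integer(D)
  items <- character(D)
  endos <- character(D)
  symptom <- integer(D)
  for (d in seq_len(D)) {
    nd <- if (cfg$couple_to == "night_before") d - 1L else d
    eta <- alpha_i
    if (nd >= 1L && nd <= length(valid) && isTRUE(valid[nd]) &&
        !is.na(m_sfi)) {
      eta <- eta + cfg$beta_sfi * (sfi100[nd] - m_sfi) +
        cfg$beta_se * (se[nd] - m_se)
    }
    y <- as.integer(stats::runif(1) < stats::plogis(eta))
    script <- build_survey_script(dates[d])
    if (y == 1L) {
      repeat {
        endo <- as.integer(stats::runif(2) < 0.55)
        if (any(endo == 1L)) break
      }
    } else {
      endo <- c(0L, 0L)
    }
    greet[d] <- script$greeting_item_id
    items[d] <- paste(script$phq_item_ids, collapse = ";")
    endos[d] <- paste(endo, collapse = ";")
    symptom[d] <- code_symptom_day(endo)
  }
  data.frame(participant_id = pid, date = dates, greeting_item_id = greet,
             phq_item_ids = items, endorsements = endos,
             symptom_binary = symptom)
}

## ---- minute streams ----------------------------------------------------

## Calendar overlay of the nightly windows for one participant:
## an integer vector of length D*1440, 1 asleep / 0 awake.
.overlay_nights <- function(nights, D, rev_cycle) {
  asleep <- integer(D * 1440L)
  for (d in seq_along(nights)) {
    x <- nights[[d]]
    if (rev_cycle) {
      # window [06:00, 24:00) of day d+1
      base <- d * 1440L + 360L # 0-based minute of window start
      asleep[(base + 1L):(base + SLEEP_WINDOW_MIN)] <- x
    } else {
      # [18:00 day d, 12:00 day d+1)
      base <- (d - 1L) * 1440L + 1080L
      asleep[(base + 1L):(base + SLEEP_WINDOW_MIN)] <- x
    }
  }
  asleep
}

.sim_participant_minutes <- function(cfg, pp, pa, nights, D, rev_cycle) {
  N <- D * 1440L
  asleep <- .overlay_nights(nights, D, rev_cycle)
  minute_of_day <- rep(0:1439, D)
  day <- rep(seq_len(D), each = 1440L)

  steps <- numeric(N)
  intensity <- rep("sedentary", N)
  tot_act <- pa$light + pa$moderate + pa$intense
  class_prob <- c(pa$light, pa$moderate, pa$intense) / tot_act

  for (d in seq_len(D)) {
    ix <- which(day == d)
    awake <- asleep[ix] == 0L
    w <- if (rev_cycle) which(awake) else which(awake & minute_of_day[ix] >= 300L)
    if (length(w) < 60L) next
    a_day <- tot_act * stats::rlnorm(1, 0, 0.25)
    props <- stats::runif(5, 0.5, 1.5)
    durs <- pmax(3L, round(a_day * props / sum(props)))
    # anchor positions in awake-minute space: one early, rest spread out
    anchors <- c(round(stats::runif(1, 5, 25)),
                 round(seq_len(4) * length(w) / 4.6 +
                         stats::runif(4, -20, 20)))
    anchors <- pmin(pmax(anchors, 1L), length(w))
    for (b in seq_len(5)) {
      pos <- anchors[b]:min(anchors[b] + durs[b] - 1L, length(w))
      mi <- ix[w[pos]]
      cls <- sample(c("light", "moderate", "intense"), length(mi),
                    replace = TRUE, prob = class_prob)
      stp <- numeric(length(mi))
      stp[cls == "light"] <- round(stats::runif(sum(cls == "light"), 3, 18))
      stp[cls == "moderate"] <- round(stats::runif(sum(cls == "moderate"), 25, 50))
      stp[cls == "intense"] <- round(stats::runif(sum(cls == "intense"), 40, 80))
      steps[mi] <- stp
      intensity[mi] <- cls
    }
    # puttering: sporadic low step counts on otherwise sedentary awake minutes
    putter <- ix[w][steps[ix[w]] == 0 & stats::runif(length(w)) < 0.12]
    steps[putter] <- round(stats::runif(length(putter), 1, 6))
  }

  # guard: no within-day inactive run of 460+ minutes (stir an awake
  # minute near the middle of any such run -- a nocturnal bathroom trip)
  for (d in seq_len(D)) {
    ix <- which(day == d)
    for (pass in 1:6) {
      inactive <- steps[ix] == 0 & intensity[ix] == "sedentary"
      r <- rle(inactive)
      ends <- cumsum(r$lengths)
      long <- which(r$values & r$lengths >= 460L)
      if (!length(long)) break
      for (i in long) {
        seg <- (ends[i] - r$lengths[i] + 1L):ends[i]
        aw <- seg[asleep[ix[seg]] == 0L]
        tgt <- if (length(aw)) aw[which.min(abs(aw - stats::median(seg)))] else seg[length(seg) %/% 2L]
        steps[ix[tgt]] <- round(stats::runif(1, 3, 10))
      }
    }
  }

  # circadian heart rate with sleep dip, activity load and AR(1) noise
  phase <- if (rev_cycle) 180L else 900L # acrophase minute of day
  circ <- pa$hr_base + cfg$hr_amp * cos(2 * pi * (minute_of_day - phase) / 1440)
  noise <- as.numeric(stats::filter(stats::rnorm(N, 0, cfg$hr_noise_sd),
                                    cfg$hr_ar, method = "recursive"))
  hr <- circ - cfg$hr_night_dip * (asleep == 1L) + steps / 10 + noise
  hr <- round(pmin(cfg$hr_clamp[2], pmax(cfg$hr_clamp[1], hr)))

  data.frame(day = day, minute = minute_of_day, heart_rate = hr,
             sleep_class = asleep, steps = steps, intensity = intensity)
}

## ---- missingness -------------------------------------------------------

#' Apply day-level missingness to a cohort
#'
#' Missingness is missing-completely-at-random at the participant-day
#' level, independently per domain. For each domain, exactly
#' `round(rate * N)` of the `N` eligible units are masked (so realized
#' marginal rates match the configured rates to rounding, and converge
#' exactly as the cohort grows): `survey` masks the day's responses,
#' `hrv` the day's heart rate, `steps` the day's steps and intensity,
#' and `sleep` masks whole nights (the night ending a morning carries
#' that day's sleep measures).
#'
#' @param cohort A `wearlab_cohort`.
#' @param rates Named vector of proportions (`survey`, `hrv`, `sleep`,
#'   `steps`); defaults to the cohort config's rates.
#' @return The cohort with masked entries plus a `missing_assignments`
#'   element listing the masked participant-days per domain.
#' @export
apply_missingness <- function(cohort, rates = cohort$config$missing_rates) {
  stopifnot(inherits(cohort, "wearlab_cohort"))
  known <- c("survey", "hrv", "sleep", "steps")
  if (is.null(names(rates)) || !all(names(rates) %in% known)) {
    stop("unknown missingness domain: ",
         paste(setdiff(names(rates), known), collapse = ", "))
  }
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  full <- stats::setNames(rep(0, 4), known)
  full[names(rates)] <- rates
  rates <- full

  days <- unique(cohort$surveys[, c("participant_id", "date")])
  nights <- cohort$sleep_nights[, c("participant_id", "night_date")]
  pick <- function(tbl, rate) {
    k <- round(rate * nrow(tbl))
    if (k <= 0L) return(tbl[0, , drop = FALSE])
    tbl[sort(sample.int(nrow(tbl), k)), , drop = FALSE]
  }
  asg <- list(survey = pick(days, rates[["survey"]]),
              hrv = pick(days, rates[["hrv"]]),
              sleep = pick(nights, rates[["sleep"]]),
              steps = pick(days, rates[["steps"]]))

  sv_key <- paste(cohort$surveys$participant_id, cohort$surveys$date)
  hit <- sv_key %in% paste(asg$survey$participant_id, asg$survey$date)
  cohort$surveys$endorsements[hit] <- NA_character_
  cohort$surveys$symptom_binary[hit] <- NA_integer_

  sn_key <- paste(cohort$sleep_nights$participant_id, cohort$sleep_nights$night_date)
  hit <- sn_key %in% paste(asg$sleep$participant_id, asg$sleep$night_date)
  if (any(hit)) {
    cohort$sleep_nights$valid[hit] <- FALSE
    for (col in c("time_in_bed", "tst", "n_awakenings", "sfi", "se",
                  "n_long_episodes", "pct_missing")) {
      cohort$sleep_nights[[col]][hit] <- NA
    }
    cohort$sleep_nights$onset[hit] <- NA_integer_
    cohort$sleep_nights$offset[hit] <- NA_integer_
    cohort$sleep_nights$onset_time[hit] <- NA_character_
    cohort$sleep_nights$offset_time[hit] <- NA_character_
  }

  if (!is.null(cohort$minutes)) {
    mk <- paste(cohort$minutes$participant_id, cohort$minutes$date)
    cohort$minutes$heart_rate[mk %in% paste(asg$hrv$participant_id, asg$hrv$date)] <- NA_real_
    sel <- mk %in% paste(asg$steps$participant_id, asg$steps$date)
    cohort$minutes$steps[sel] <- NA_real_
    cohort$minutes$intensity[sel] <- NA_character_
    # a masked night blanks the sleep classification across its window
    if (nrow(asg$sleep)) {
      rev_ids <- cohort$profiles$participant_id[cohort$profiles$reversed_cycle]
      for (j in seq_len(nrow(asg$sleep))) {
        pid <- asg$sleep$participant_id[j]
        nd <- asg$sleep$night_date[j]
        rev <- pid %in% rev_ids
        if (rev) {
          sel <- cohort$minutes$participant_id == pid &
            cohort$minutes$date == nd + 1L & cohort$minutes$minute >= 360L
        } else {
          sel <- cohort$minutes$participant_id == pid &
            ((cohort$minutes$date == nd & cohort$minutes$minute >= 1080L) |
               (cohort$minutes$date == nd + 1L & cohort$minutes$minute < 720L))
        }
        cohort$minutes$sleep_class[sel] <- NA_integer_
      }
    }
  }

  cohort$missing_assignments <- asg
  cohort
}
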