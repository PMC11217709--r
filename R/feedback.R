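## Individualized traffic-light feedback and emergency alerts.
##
## Each user's first calendar week of participation defines a per-domain
## baseline (mean and sample SD). A day's value is classified green when
## it exceeds mean + 1 SD, red when it falls below mean - 1 SD, yellow
## within the band (boundaries inclusive to yellow), gray when the value
## is missing or the baseline invalid. For the sleep domain (keyed on the
## fragmentation index, where higher means worse sleep) green and red are
## swapped.

FEEDBACK_DOMAINS <- c("stress_hf", "sleep_sfi", "steps", "activity")

EMERGENCY_THRESHOLDS <- list(inactive_min = 480L, hr_low = 30, hr_high = 140)

#' First-week baseline statistics per domain
#'
#' @param daily Data frame with `participant_id`, `date`, `domain`,
#'   `value` (one row per participant-day-domain; missing days may be
#'   absent or carry `NA`).
#' @param week1_start Optional named vector/list of each participant's
#'   first day; defaults to the participant's earliest date in `daily`.
#' @return Data frame `participant_id`, `domain`, `mean`, `sd` (sample,
#'   n-1), `n_days`, `valid` (at least 2 non-missing week-1 days).
#' @export
compute_baseline <- function(daily, week1_start = NULL) {
  out <- list()
  for (pid in unique(daily$participant_id)) {
    d <- daily[daily$participant_id == pid, , drop = FALSE]
    start <- if (!is.null(week1_start)) as.Date(week1_start[[pid]]) else min(d$date)
    wk1 <- d[d$date >= start & d$date < start + 7L, , drop = FALSE]
    for (dom in unique(daily$domain)) {
      v <- wk1$value[wk1$domain == dom]
      v <- v[!is.na(v)]
      out[[length(out) + 1L]] <- data.frame(
        participant_id = pid, domain = dom,
        mean = if (length(v)) mean(v) else NA_real_,
        sd = if (length(v) >= 2L) stats::sd(v) else NA_real_,
        n_days = length(v), valid = length(v) >= 2L)
    }
  }
  do.call(rbind, out)
}

#' Classify one day's value against a baseline
#'
#' @param value Numeric daily value (`NA` allowed).
#' @param mean,sd Baseline statistics.
#' @param domain One of `"stress_hf"`, `"sleep_sfi"`, `"steps"`,
#'   `"activity"`; green/red are inverted for `"sleep_sfi"`.
#' @param valid Baseline validity flag; an invalid baseline yields gray.
#' @return `"green"`, `"yellow"`, `"red"`, or `"gray"`.
#' @export
classify_day <- function(value, mean, sd, domain, valid = TRUE) {
  domain <- match.arg(domain, FEEDBACK_DOMAINS)
  if (!isTRUE(valid) || is.na(value) || is.na(mean) || is.na(sd)) return("gray")
  color <- if (value > mean + sd) "green"
           else if (value < mean - sd) "red"
           else "yellow"
  if (domain == "sleep_sfi") {
    color <- switch(color, green = "red", red = "green", color)
  }
  color
}

#' Daily feedback cards for a cohort
#'
#' Builds the per-domain daily value table (stress = daily mean HF power,
#' sleep = nightly fragmentation index of the night ending that morning,
#' steps = daily step total, activity = light + moderate + intense
#' minutes), computes first-week baselines, and classifies every
#' participant-day.
#'
#' @param hrv_day Output of [hrv_daily()].
#' @param sleep_nights Output of [score_sleep_nights()].
#' @param act_day Output of [activity_daily()].
#' @return List with `cards` (one row per participant-day: colors,
#'   values, deltas from baseline mean) and `baselines`.
#' @export
feedback_cards <- function(hrv_day, sleep_nights, act_day) {
  long <- rbind(
    data.frame(participant_id = hrv_day$participant_id, date = hrv_day$date,
               domain = "stress_hf", value = hrv_day$mean_hf),
    {
      sn <- sleep_nights[sleep_nights$valid, , drop = FALSE]
      data.frame(participant_id = sn$participant_id,
                 date = sn$night_date + 1L, # the morning the night ends
                 domain = "sleep_sfi", value = sn$sfi)
    },
    data.frame(participant_id = act_day$participant_id, date = act_day$date,
               domain = "steps", value = act_day$steps),
    data.frame(participant_id = act_day$participant_id, date = act_day$date,
               domain = "activity",
               value = act_day$light_min + act_day$moderate_min +
                 act_day$intense_min))
  long <- long[!is.na(long$value), , drop = FALSE]
  base <- compute_baseline(long)
  all_days <- unique(long[, c("participant_id", "date")])
  cards <- all_days[order(all_days$participant_id, all_days$date), , drop = FALSE]
  for (dom in FEEDBACK_DOMAINS) {
    dv <- long[long$domain == dom, , drop = FALSE]
    ix <- match(paste(cards$participant_id, cards$date),
                paste(dv$participant_id, dv$date))
    val <- dv$value[ix]
    bx <- match(paste(cards$participant_id, dom),
                paste(base$participant_id, base$domain))
    bm <- base$mean[bx]; bs <- base$sd[bx]; bv <- base$valid[bx]
    col <- vapply(seq_len(nrow(cards)), function(i) {
      classify_day(val[i], bm[i], bs[i], dom, valid = isTRUE(bv[i]))
    }, character(1))
    cards[[paste0(dom, "_value")]] <- val
    cards[[paste0(dom, "_delta")]] <- val - bm
    cards[[paste0(dom, "_color")]] <- col
  }
  rownames(cards) <- NULL
  list(cards = cards, baselines = base)
}

#' Detect emergency alerts in a minute stream
#'
#' Evaluates three independent triggers per participant-day: heart rate
#' below 30 bpm, heart rate above 140 bpm (both strict), and an inactive
#' run exceeding 480 minutes (strictly more than 8 hours; inactive =
#' zero/missing steps with sedentary or missing intensity). One alert per
#' trigger per day, stamped at the first crossing.
#'
#' @param minutes Minute-record data frame.
#' @param thresholds List with `inactive_min`, `hr_low`, `hr_high`.
#' @return Data frame `participant_id`, `timestamp`, `trigger`, `value`.
#' @export
detect_emergencies <- function(minutes, thresholds = EMERGENCY_THRESHOLDS) {
  alerts <- list()
  push <- function(pid, date, minute, trigger, value) {
    ts <- sprintf("%sT%02d:%02d", format(date, "%Y-%m-%d"),
                  minute %/% 60L, minute %% 60L)
    alerts[[length(alerts) + 1L]] <<- data.frame(
      participant_id = pid, timestamp = ts, trigger = trigger, value = value)
  }
  key <- paste(minutes$participant_id, format(minutes$date), sep = "|")
  for (ix in split(seq_len(nrow(minutes)), key)) {
    sub <- minutes[ix, , drop = FALSE]
    sub <- sub[order(sub$minute), , drop = FALSE]
    pid <- sub$participant_id[1]; date <- sub$date[1]
    low <- which(!is.na(sub$heart_rate) & sub$heart_rate < thresholds$hr_low)
    if (length(low)) push(pid, date, sub$minute[low[1]], "hr_low",
                          sub$heart_rate[low[1]])
    high <- which(!is.na(sub$heart_rate) & sub$heart_rate > thresholds$hr_high)
    if (length(high)) push(pid, date, sub$minute[high[1]], "hr_high",
                           sub$heart_rate[high[1]])
    inactive <- (is.na(sub$steps) | sub$steps == 0) &
      (is.na(sub$intensity) | sub$intensity == "sedentary")
    run <- 0L
    for (i in seq_along(inactive)) {
      run <- if (inactive[i]) run + 1L else 0L
      if (run == thresholds$inactive_min + 1L) {
        push(pid, date, sub$minute[i], "inactivity_gt_8h", run)
        break
      }
    }
  }
  if (!length(alerts)) {
    return(data.frame(participant_id = character(), timestamp = character(),
                      trigger = character(), value = numeric()))
  }
  out <- do.call(rbind, alerts)
  rownames(out) <- NULL
  out
}
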