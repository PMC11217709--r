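## Nightly sleep scoring from minute-level sleep/wake classification.
##
## Minute classes are coded as integers throughout this file:
##   1 = asleep, 0 = awake, NA = missing (device off / not classified).
## Missing minutes break runs: they are neither asleep nor awake, so a
## rule window or a consecutive-sleep run never spans a gap.

SLEEP_WINDOW_MIN <- 18L * 60L # 1080 minutes: 6 PM -> noon next day

#' Extract the nightly scoring window from a minute stream
#'
#' The scoring window for a night runs from 6 PM of `night_date` to noon
#' of the following day (1080 minutes). For a participant whose day and
#' night cycles are reversed, the window instead covers 6 AM to midnight
#' of the day after `night_date`, so that every night's window still ends
#' before the morning it predicts.
#'
#' @param minutes Data frame of minute records with columns
#'   `participant_id`, `date` (class `Date`), `minute` (0-1439 minute of
#'   day) and `sleep_class` (integer 1 = asleep, 0 = awake, NA = missing).
#' @param night_date `Date`; the evening the window starts (standard
#'   window) or the day before the daytime sleep period (reversed window).
#' @param reversed_cycle Logical; use the daytime window for a
#'   day/night-reversed sleeper.
#' @return A list of class `sleep_window` with elements `participant_id`,
#'   `night_date`, `reversed_cycle`, and `classes` — an integer vector of
#'   length 1080 with absent minutes filled as `NA`.
#' @export
extract_sleep_window <- function(minutes, night_date, reversed_cycle = FALSE) {
  night_date <- as.Date(night_date)
  if (reversed_cycle) {
    # daytime window [06:00, 24:00) of the day following night_date
    day1 <- night_date + 1L
    sel1 <- minutes$date == day1 & minutes$minute >= 360L
    idx1 <- minutes$minute[sel1] - 360L + 1L
    classes <- rep(NA_integer_, SLEEP_WINDOW_MIN)
    classes[idx1] <- minutes$sleep_class[sel1]
  } else {
    # [18:00 night_date, 12:00 next day)
    day2 <- night_date + 1L
    sel1 <- minutes$date == night_date & minutes$minute >= 1080L
    sel2 <- minutes$date == day2 & minutes$minute < 720L
    classes <- rep(NA_integer_, SLEEP_WINDOW_MIN)
    classes[minutes$minute[sel1] - 1080L + 1L] <- minutes$sleep_class[sel1]
    classes[minutes$minute[sel2] + 360L + 1L] <- minutes$sleep_class[sel2]
  }
  structure(
    list(participant_id = if (nrow(minutes)) minutes$participant_id[[1]] else NA_character_,
         night_date = night_date, reversed_cycle = reversed_cycle,
         classes = classes),
    class = "sleep_window")
}

## Run-length segments of a class vector, with NA as its own class (2).
## Returns plain vectors (kept off data.frame for speed in hot loops).
.sleep_runs <- function(x) {
  x2 <- x
  x2[is.na(x2)] <- 2L
  r <- rle(x2)
  ends <- cumsum(r$lengths)
  list(value = r$values, length = r$lengths,
       start = ends - r$lengths + 1L, end = ends)
}

#' Rescore a nightly sleep/wake series
#'
#' Applies the actigraphy rescoring criteria to a minute-level sleep/wake
#' vector, in order, each rule over the output of the previous:
#' \enumerate{
#'   \item The first minute of a sleep period preceded by at least 4 awake
#'     minutes: kept as sleep under `rule1_direction = "as_printed"`, or
#'     rescored to awake under `"webster"` (the direction in the classic
#'     actigraphy rescoring literature).
#'   \item After 10 or more awake minutes, the first (up to) 3 minutes of
#'     the following sleep period are rescored to awake. Applied in a
#'     single pass over a snapshot of the series (extensions created by
#'     the rule do not cascade within the pass).
#'   \item (with 4) A sleep period shorter than 6 minutes flanked by more than
#'     15 awake minutes on both sides is rescored to awake.
#'   \item A sleep period shorter than 10 minutes flanked by more than 20
#'     awake minutes on both sides is rescored to awake.
#' }
#' Missing minutes break runs and are never relabelled.
#'
#' @param x Integer vector (1 asleep / 0 awake / NA) or a `sleep_window`.
#' @param rule1_direction `"as_printed"` (default) or `"webster"`.
#' @return Same type as the input, with rescored classes.
#' @export
rescore_sleep <- function(x, rule1_direction = c("as_printed", "webster")) {
  rule1_direction <- match.arg(rule1_direction)
  win <- NULL
  if (inherits(x, "sleep_window")) {
    win <- x
    x <- x$classes
  }
  stopifnot(is.numeric(x) || is.logical(x))
  x <- as.integer(x)
  if (length(x)) {
    x <- .rescore_rule1(x, rule1_direction)
    x <- .rescore_rule2(x)
    x <- .rescore_isolated(x, max_sleep = 5L, min_flank = 16L)  # rules 3/4
    x <- .rescore_isolated(x, max_sleep = 9L, min_flank = 21L)  # rule 5
  }
  if (!is.null(win)) {
    win$classes <- x
    win$rule1_direction <- rule1_direction
    return(win)
  }
  x
}

.rescore_rule1 <- function(x, direction) {
  runs <- .sleep_runs(x)
  out <- x # conditions evaluate against the stage input, not the output
  for (i in which(runs$value == 1L)) {
    s <- runs$start[i]
    if (s >= 5L && isTRUE(all(x[(s - 4L):(s - 1L)] == 0L))) {
      # previous 4 minutes all awake (non-missing)
      out[s] <- if (direction == "webster") 0L else 1L
    }
  }
  out
}

.rescore_rule2 <- function(x) {
  runs <- .sleep_runs(x)
  out <- x
  for (i in which(runs$value == 0L & runs$length >= 10L)) {
    j <- runs$end[i] + 1L
    k <- 0L
    while (k < 3L && j <= length(x) && !is.na(x[j]) && x[j] == 1L) {
      out[j] <- 0L
      j <- j + 1L
      k <- k + 1L
    }
  }
  out
}

## Rules 3/4 and 5: short sleep bouts with long awake flanks on both sides.
.rescore_isolated <- function(x, max_sleep, min_flank) {
  runs <- .sleep_runs(x)
  out <- x
  nr <- length(runs$value)
  for (i in which(runs$value == 1L & runs$length <= max_sleep)) {
    if (i == 1L || i == nr) next                  # no flank at an edge
    if (runs$value[i - 1L] == 0L && runs$length[i - 1L] >= min_flank &&
        runs$value[i + 1L] == 0L && runs$length[i + 1L] >= min_flank) {
      out[runs$start[i]:runs$end[i]] <- 0L
    }
  }
  out
}

#' Detect sleep onset and offset
#'
#' Onset is the start of the first run of at least 10 consecutive asleep
#' minutes; offset is the end of the last such run. Missing minutes break
#' runs.
#'
#' @param x Rescored class vector or `sleep_window`.
#' @return List with `onset`, `offset` (1-based minute indices into the
#'   window) and `valid` (`FALSE` when no qualifying run exists).
#' @export
detect_onset_offset <- function(x) {
  if (inherits(x, "sleep_window")) x <- x$classes
  runs <- .sleep_runs(as.integer(x))
  ok <- runs$value == 1L & runs$length >= 10L
  if (!any(ok)) {
    return(list(onset = NA_integer_, offset = NA_integer_, valid = FALSE))
  }
  list(onset = runs$start[which(ok)[1]],
       offset = runs$end[which(ok)[sum(ok)]],
       valid = TRUE)
}

#' Compute nightly sleep metrics
#'
#' Within the inclusive onset-offset span: time in bed is the inclusive
#' minute count; total sleep time (TST) is the number of asleep minutes;
#' an awakening is an awake run of 2 or more consecutive minutes (awake
#' "for more than 1 minute"); the sleep fragmentation index (SFI) is the
#' number of such awakenings per minute of TST; sleep efficiency (SE) is
#' 100 * TST / time in bed; long fragmentation episodes are awake runs of
#' at least `long_episode_min` minutes. Nights with more than
#' `max_missing_pct` percent missing minutes inside the span, or with no
#' valid onset, are flagged invalid.
#'
#' @param x Rescored class vector or `sleep_window`.
#' @param onset,offset Minute indices as returned by
#'   [detect_onset_offset()]; detected automatically when omitted.
#' @param long_episode_min Minimum length (minutes) of a "long"
#'   fragmentation episode (default 5).
#' @param max_missing_pct Maximum tolerated percentage of missing minutes
#'   within the onset-offset span (default 20).
#' @return One-row data frame with columns `valid`, `time_in_bed`, `tst`,
#'   `onset`, `offset`, `n_awakenings`, `sfi`, `se`, `n_long_episodes`,
#'   `pct_missing`.
#' @export
sleep_metrics <- function(x, onset = NULL, offset = NULL,
                          long_episode_min = 5L, max_missing_pct = 20) {
  as.data.frame(.sleep_metrics_list(x, onset, offset, long_episode_min,
                                    max_missing_pct))
}

## list-returning core kept off data.frame for hot loops
.sleep_metrics_list <- function(x, onset = NULL, offset = NULL,
                                long_episode_min = 5L, max_missing_pct = 20) {
  if (inherits(x, "sleep_window")) x <- x$classes
  x <- as.integer(x)
  if (is.null(onset) || is.null(offset)) {
    oo <- detect_onset_offset(x)
    onset <- oo$onset
    offset <- oo$offset
    if (!oo$valid) {
      return(list(valid = FALSE, time_in_bed = NA_real_, tst = NA_real_,
                  onset = NA_integer_, offset = NA_integer_,
                  n_awakenings = NA_integer_, sfi = NA_real_,
                  se = NA_real_, n_long_episodes = NA_integer_,
                  pct_missing = NA_real_))
    }
  }
  seg <- x[onset:offset]
  tib <- offset - onset + 1L
  tst <- sum(seg == 1L, na.rm = TRUE)
  runs <- .sleep_runs(seg)
  awake <- runs$value == 0L
  n_awak <- sum(awake & runs$length >= 2L)
  n_long <- sum(awake & runs$length >= long_episode_min)
  pct_missing <- 100 * mean(is.na(seg))
  valid <- tst > 0L && pct_missing <= max_missing_pct
  list(valid = valid, time_in_bed = as.numeric(tib),
       tst = as.numeric(tst), onset = onset, offset = offset,
       n_awakenings = n_awak,
       sfi = if (tst > 0L) n_awak / tst else NA_real_,
       se = 100 * tst / tib, n_long_episodes = n_long,
       pct_missing = pct_missing)
}

#' Convert a 1-based window minute index to a "YYYY-MM-DDTHH:MM" stamp
#'
#' Standard windows start at 18:00 of the night date; reversed-cycle
#' windows at 06:00 of the following day.
#'
#' @param night_date `Date`; the night the window belongs to.
#' @param idx 1-based minute index into the 1080-minute window (NA allowed).
#' @param reversed_cycle Logical.
#' @return Character timestamp, local time, no zone suffix.
#' @export
window_minute_to_timestamp <- function(night_date, idx, reversed_cycle = FALSE) {
  night_date <- as.Date(night_date)
  out <- rep(NA_character_, length(idx))
  ok <- !is.na(idx)
  if (!any(ok)) return(out)
  start_min <- if (reversed_cycle) 360L else 1080L
  start_date <- if (reversed_cycle) night_date + 1L else night_date
  abs_min <- start_min + as.integer(idx[ok]) - 1L
  d <- start_date + abs_min %/% 1440L
  m <- abs_min %% 1440L
  out[ok] <- sprintf("%sT%02d:%02d", format(d, "%Y-%m-%d"), m %/% 60L, m %% 60L)
  out
}

#' Score every night of a cohort minute stream
#'
#' Runs window extraction, rescoring, onset/offset detection and metric
#' computation for each participant-night and returns the nightly metrics
#' table (one row per participant and night date).
#'
#' @param minutes Minute-record data frame (see [generate_cohort()]).
#' @param profiles Participant table with `participant_id` and
#'   `reversed_cycle`.
#' @param rule1_direction Passed to [rescore_sleep()].
#' @param long_episode_min,max_missing_pct Passed to [sleep_metrics()].
#' @return Data frame with one row per participant-night: identifiers,
#'   validity flag, `time_in_bed`, `tst`, onset/offset timestamps,
#'   `n_awakenings`, `sfi`, `se`, `n_long_episodes`, `rule1_direction`
#'   and `pct_missing`.
#' @export
score_sleep_nights <- function(minutes, profiles,
                               rule1_direction = c("as_printed", "webster"),
                               long_episode_min = 5L, max_missing_pct = 20) {
  rule1_direction <- match.arg(rule1_direction)
  res <- list()
  for (pid in unique(minutes$participant_id)) {
    pm <- minutes[minutes$participant_id == pid, , drop = FALSE]
    rev_cycle <- isTRUE(profiles$reversed_cycle[profiles$participant_id == pid][1])
    dates <- sort(unique(pm$date))
    # last night needs the following morning; score nights whose window is
    # fully covered by the stream
    nights <- dates[dates < max(dates)]
    for (nd in as.list(nights)) {
      win <- extract_sleep_window(pm, nd, rev_cycle)
      win <- rescore_sleep(win, rule1_direction)
      m <- sleep_metrics(win, long_episode_min = long_episode_min,
                         max_missing_pct = max_missing_pct)
      m <- cbind(data.frame(participant_id = pid,
                            night_date = as.Date(nd)), m)
      m$onset_time <- window_minute_to_timestamp(as.Date(nd), m$onset, rev_cycle)
      m$offset_time <- window_minute_to_timestamp(as.Date(nd), m$offset, rev_cycle)
      m$rule1_direction <- rule1_direction
      res[[length(res) + 1L]] <- m
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
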