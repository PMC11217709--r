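## Heart-rate-variability metrics from minute-level heart rate.
##
## Minute-level heart rate cannot carry true beat-to-beat variability;
## hr_to_rr() reconstructs an R-R series by replicating the implied
## interval within each minute. This is an explicit approximation (the
## within-window variability it yields comes from minute-to-minute heart
## rate changes only) and every window row carries the `rr_source` flag.
## Beat-level R-R series produced synthetically can be fed straight into
## filter_rr()/hrv_window_metrics() so that spectral behaviour is tested
## on signals that actually contain beat-scale structure.

HRV_BANDS <- list(vlf = c(0.0033, 0.04), lf = c(0.04, 0.15), hf = c(0.15, 0.40))

#' Convert minute heart rates to an R-R interval series
#'
#' Each minute with heart rate `h` (bpm) contributes `round(h)` intervals
#' of `60000 / h` milliseconds. Non-positive or missing heart rates are
#' skipped and counted.
#'
#' @param hr Numeric vector of minute heart rates in bpm.
#' @return List with `intervals` (ms), `n_skipped_minutes`, and
#'   `rr_source = "minute_reconstruction"`.
#' @export
hr_to_rr <- function(hr) {
  bad <- is.na(hr) | hr <= 0
  good <- hr[!bad]
  intervals <- rep(60000 / good, times = round(good))
  list(intervals = as.numeric(intervals),
       n_skipped_minutes = sum(bad),
       rr_source = "minute_reconstruction")
}

#' Filter an R-R interval series
#'
#' Removes intervals outside the plausible 300-2000 ms band, then
#' intervals deviating from an 11-point running median by more than 20
#' percent.
#'
#' @param intervals Numeric vector of R-R intervals in ms.
#' @return List with `intervals` (kept), `n_removed_absolute`,
#'   `n_removed_relative`, `valid` (`FALSE` when nothing survives).
#' @export
filter_rr <- function(intervals) {
  x <- intervals[!is.na(intervals)]
  in_band <- x >= 300 & x <= 2000
  n_abs <- sum(!in_band)
  x <- x[in_band]
  n_rel <- 0L
  if (length(x) >= 2L) {
    k <- min(11L, length(x))
    if (k %% 2L == 0L) k <- k - 1L
    med <- if (k >= 3L) stats::runmed(x, k, endrule = "median") else rep(stats::median(x), length(x))
    keep <- abs(x - med) <= 0.2 * med
    n_rel <- sum(!keep)
    x <- x[keep]
  }
  list(intervals = x, n_removed_absolute = n_abs, n_removed_relative = n_rel,
       valid = length(x) > 0L)
}

## One-sided periodogram band powers of an unevenly sampled interval
## series: cubic interpolation onto an fs Hz grid, mean removal, FFT.
## Total power over all one-sided bins equals the variance of the
## resampled series (Parseval), so band sums never exceed it.
.rr_band_powers <- function(intervals, fs = 4) {
  t <- cumsum(intervals) / 1000 # seconds, time of each beat
  t <- t - t[1]
  if (length(intervals) < 4L || t[length(t)] <= 1) {
    return(list(vlf = NA_real_, lf = NA_real_, hf = NA_real_))
  }
  grid <- seq(0, t[length(t)], by = 1 / fs)
  xi <- stats::spline(t, intervals, xout = grid, method = "fmm")$y
  n <- length(xi)
  xi <- xi - mean(xi)
  sp <- Mod(stats::fft(xi))^2 / n^2
  kmax <- floor(n / 2)
  if (kmax < 1L) return(list(vlf = NA_real_, lf = NA_real_, hf = NA_real_))
  freq <- (1:kmax) * fs / n
  # one-sided: double interior bins; the Nyquist bin (even n) is unique
  mult <- rep(2, kmax)
  if (n %% 2L == 0L) mult[kmax] <- 1
  p1 <- sp[2:(kmax + 1L)] * mult
  band <- function(lim) sum(p1[freq > lim[1] & freq <= lim[2]])
  list(vlf = band(HRV_BANDS$vlf), lf = band(HRV_BANDS$lf), hf = band(HRV_BANDS$hf))
}

#' Time- and frequency-domain HRV metrics for one 5-minute window
#'
#' SDNN is the population standard deviation of the intervals, RMSSD the
#' root mean square of successive differences. Spectral powers come from
#' a periodogram of the evenly resampled (4 Hz, cubic interpolation)
#' interval series after mean removal, integrated over VLF
#' 0.0033-0.04 Hz, LF 0.04-0.15 Hz and HF 0.15-0.40 Hz; the ratio is
#' LF/HF.
#'
#' @param intervals Filtered R-R intervals (ms) belonging to one window.
#' @param window_start Optional timestamp carried through to the output.
#' @param min_intervals Minimum interval count for a valid window
#'   (default 30).
#' @param fs Resampling rate in Hz for the spectral estimate.
#' @return One-row data frame: `window_start`, `n_intervals`, `sdnn`,
#'   `rmssd`, `vlf`, `lf`, `hf`, `lf_hf`, `valid`.
#' @export
hrv_window_metrics <- function(intervals, window_start = NA_character_,
                               min_intervals = 30L, fs = 4) {
  as.data.frame(.hrv_window_metrics_list(intervals, window_start,
                                         min_intervals, fs))
}

## list-returning core kept off data.frame for hot loops
.hrv_window_metrics_list <- function(intervals, window_start = NA_character_,
                                     min_intervals = 30L, fs = 4) {
  n <- length(intervals)
  if (n < min_intervals) {
    return(list(window_start = window_start, n_intervals = n,
                sdnn = NA_real_, rmssd = NA_real_, vlf = NA_real_,
                lf = NA_real_, hf = NA_real_, lf_hf = NA_real_,
                valid = FALSE))
  }
  sdnn <- sqrt(mean((intervals - mean(intervals))^2))
  rmssd <- sqrt(mean(diff(intervals)^2))
  bp <- .rr_band_powers(intervals, fs = fs)
  lf_hf <- if (!is.na(bp$hf) && bp$hf > 0) bp$lf / bp$hf else NA_real_
  list(window_start = window_start, n_intervals = n, sdnn = sdnn,
       rmssd = rmssd, vlf = bp$vlf, lf = bp$lf, hf = bp$hf,
       lf_hf = lf_hf, valid = TRUE)
}

#' Compute HRV windows for a cohort minute stream
#'
#' Minutes are grouped into non-overlapping 5-minute windows aligned to
#' clock boundaries (:00, :05, ...); each window's heart rates are
#' converted to R-R intervals, filtered, and summarised.
#'
#' @param minutes Minute-record data frame with `participant_id`, `date`,
#'   `minute`, `heart_rate`.
#' @param min_intervals Passed to [hrv_window_metrics()].
#' @return Data frame of window rows (`participant_id`, `date`,
#'   `window_start`, metrics, `valid`).
#' @export
hrv_windows <- function(minutes, min_intervals = 30L) {
  ok <- !is.na(minutes$heart_rate)
  mm <- minutes[ok, c("participant_id", "date", "minute", "heart_rate")]
  if (!nrow(mm)) {
    return(data.frame(participant_id = character(), date = as.Date(character()),
                      window_start = character(), n_intervals = integer(),
                      sdnn = numeric(), rmssd = numeric(), vlf = numeric(),
                      lf = numeric(), hf = numeric(), lf_hf = numeric(),
                      valid = logical()))
  }
  mm$block <- mm$minute %/% 5L
  datestr <- format(mm$date, "%Y-%m-%d")
  key <- paste(mm$participant_id, datestr, mm$block, sep = "|")
  pieces <- split(seq_len(nrow(mm)), key)
  hr_all <- mm$heart_rate
  rows <- lapply(pieces, function(ix) {
    start_min <- mm$block[ix[1]] * 5L
    ts <- sprintf("%sT%02d:%02d", datestr[ix[1]],
                  start_min %/% 60L, start_min %% 60L)
    rr <- hr_to_rr(hr_all[ix])
    fl <- filter_rr(rr$intervals)
    c(list(pid = mm$participant_id[ix[1]], date = datestr[ix[1]]),
      .hrv_window_metrics_list(fl$intervals, window_start = ts,
                               min_intervals = min_intervals))
  })
  cols <- names(rows[[1]])
  out <- as.data.frame(lapply(stats::setNames(cols, cols), function(cn) {
    unlist(lapply(rows, `[[`, cn), use.names = FALSE)
  }))
  names(out)[names(out) == "pid"] <- "participant_id"
  out$date <- as.Date(out$date)
  out <- out[order(out$participant_id, out$window_start), ]
  rownames(out) <- NULL
  out
}

#' Daily HRV summaries
#'
#' Unweighted means of SDNN, RMSSD, HF power and LF/HF over the valid
#' windows of each participant-day; days without a valid window are
#' omitted (missing for HRV).
#'
#' @param windows Output of [hrv_windows()].
#' @return Data frame `participant_id`, `date`, `mean_sdnn`,
#'   `mean_rmssd`, `mean_hf`, `mean_lf_hf`, `n_valid_windows`.
#' @export
hrv_daily <- function(windows) {
  w <- windows[windows$valid, , drop = FALSE]
  if (!nrow(w)) {
    return(data.frame(participant_id = character(), date = as.Date(character()),
                      mean_sdnn = numeric(), mean_rmssd = numeric(),
                      mean_hf = numeric(), mean_lf_hf = numeric(),
                      n_valid_windows = integer()))
  }
  key <- interaction(w$participant_id, format(w$date), drop = TRUE)
  agg <- function(v) tapply(v, key, mean, na.rm = TRUE)
  first <- !duplicated(key)
  out <- data.frame(participant_id = w$participant_id[first],
                    date = w$date[first])
  ord <- match(interaction(out$participant_id, format(out$date), drop = TRUE),
               levels(key))
  out$mean_sdnn <- as.numeric(agg(w$sdnn))[ord]
  out$mean_rmssd <- as.numeric(agg(w$rmssd))[ord]
  out$mean_hf <- as.numeric(agg(w$hf))[ord]
  out$mean_lf_hf <- as.numeric(agg(w$lf_hf))[ord]
  out$n_valid_windows <- as.integer(tapply(rep(1L, nrow(w)), key, sum))[ord]
  out <- out[order(out$participant_id, out$date), ]
  rownames(out) <- NULL
  out
}

#' Synthesize a beat-level R-R series with sinusoidal modulation
#'
#' Generates beat times whose intervals oscillate around `base_ms` at
#' `freq` Hz with amplitude `amp_ms`, for spectral validation of the
#' frequency-domain metrics on signals that genuinely contain
#' beat-scale structure.
#'
#' @param duration_s Length of the series in seconds (default 300, one
#'   analysis window).
#' @param base_ms Mean interval in ms.
#' @param freq Modulation frequency in Hz.
#' @param amp_ms Modulation amplitude in ms.
#' @param noise_ms SD of additive white noise per beat (default 0).
#' @return Numeric vector of R-R intervals (ms).
#' @export
synth_rr_series <- function(duration_s = 300, base_ms = 1000, freq = 0.25,
                            amp_ms = 50, noise_ms = 0) {
  t <- 0
  out <- numeric(0)
  while (t < duration_s) {
    rr <- base_ms + amp_ms * sin(2 * pi * freq * t)
    if (noise_ms > 0) rr <- rr + stats::rnorm(1, 0, noise_ms)
    out <- c(out, rr)
    t <- t + rr / 1000
  }
  out
}
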