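## Day-level analysis table and multilevel logistic models.
##
## Each analysis day carries the previous night's sleep metrics (the
## night ending that morning), the day's HRV and activity summaries, the
## same-day symptom binary and the next calendar day's binary. Daily
## predictors are person-mean centered over each participant's retained
## analysis days; person-level covariates are grand-mean centered. The
## fragmentation index enters the models as awakenings per 100 minutes
## of sleep (SFI x 100) so that a unit change is interpretable; sleep
## efficiency enters in percent.

DAILY_PREDICTORS <- c("lf_hf", "hf", "sdnn", "rmssd", "tst", "sfi", "se",
                      "steps", "light_min", "moderate_min", "intense_min")

#' Assemble the day-level analysis table
#'
#' @param sleep_nights Nightly metrics ([score_sleep_nights()] or the
#'   generator's `sleep_nights`).
#' @param surveys Daily survey table with `symptom_binary`.
#' @param profiles Participant table.
#' @param hrv_day Optional [hrv_daily()] output.
#' @param act_day Optional [activity_daily()] output.
#' @param skip_week1 Drop each participant's first 7 calendar days (the
#'   adaptation week; default `TRUE`).
#' @return Data frame with one row per retained participant-day: raw
#'   predictors, `<var>_c` person-mean-centered versions, grand-mean
#'   centered covariates (`age_gm`, `sex_gm`, `chronic_gm`, `gds_gm`),
#'   `symptom_binary` and `symptom_next_day`.
#' @export
assemble_daily_table <- function(sleep_nights, surveys, profiles,
                                 hrv_day = NULL, act_day = NULL,
                                 skip_week1 = TRUE) {
  key <- paste(surveys$participant_id, surveys$date)
  if (anyDuplicated(key)) stop("duplicate participant-date keys in surveys")
  rows <- surveys[, c("participant_id", "date", "symptom_binary")]

  nxt <- match(paste(rows$participant_id, rows$date + 1L), key)
  rows$symptom_next_day <- rows$symptom_binary[nxt]

  sn <- sleep_nights[sleep_nights$valid %in% TRUE, , drop = FALSE]
  six <- match(paste(rows$participant_id, rows$date - 1L),
               paste(sn$participant_id, sn$night_date))
  rows$tst <- sn$tst[six]
  rows$sfi <- 100 * sn$sfi[six] # model scale: awakenings / 100 min TST
  rows$sfi_raw <- sn$sfi[six]
  rows$se <- sn$se[six]

  if (!is.null(hrv_day)) {
    hix <- match(paste(rows$participant_id, rows$date),
                 paste(hrv_day$participant_id, hrv_day$date))
    rows$lf_hf <- hrv_day$mean_lf_hf[hix]
    rows$hf <- hrv_day$mean_hf[hix]
    rows$sdnn <- hrv_day$mean_sdnn[hix]
    rows$rmssd <- hrv_day$mean_rmssd[hix]
  } else {
    rows$lf_hf <- rows$hf <- rows$sdnn <- rows$rmssd <- NA_real_
  }
  if (!is.null(act_day)) {
    aix <- match(paste(rows$participant_id, rows$date),
                 paste(act_day$participant_id, act_day$date))
    rows$steps <- act_day$steps[aix]
    rows$light_min <- act_day$light_min[aix]
    rows$moderate_min <- act_day$moderate_min[aix]
    rows$intense_min <- act_day$intense_min[aix]
  } else {
    rows$steps <- rows$light_min <- rows$moderate_min <- rows$intense_min <- NA_real_
  }

  if (skip_week1) {
    keep <- logical(nrow(rows))
    for (pid in unique(rows$participant_id)) {
      sel <- rows$participant_id == pid
      keep[sel] <- rows$date[sel] >= min(rows$date[sel]) + 7L
    }
    rows <- rows[keep, , drop = FALSE]
  }

  # person-mean centering of daily predictors over retained days
  for (v in DAILY_PREDICTORS) {
    pm <- tapply(rows[[v]], rows$participant_id, mean, na.rm = TRUE)
    rows[[paste0(v, "_c")]] <- rows[[v]] - as.numeric(pm[rows$participant_id])
  }

  # grand-mean centered level-2 covariates
  pix <- match(rows$participant_id, profiles$participant_id)
  sex_w <- as.numeric(profiles$sex == "woman")
  rows$age_gm <- profiles$age[pix] - mean(profiles$age)
  rows$sex_gm <- sex_w[pix] - mean(sex_w)
  rows$chronic_gm <- profiles$n_chronic[pix] - mean(profiles$n_chronic)
  rows$gds_gm <- profiles$baseline_gds[pix] - mean(profiles$baseline_gds)
  rownames(rows) <- NULL
  rows
}

#' Fit one random-intercept multilevel logistic model
#'
#' Regresses the daily symptom binary (same-day or next-day) on one
#' person-mean-centered daily predictor plus the four grand-mean-centered
#' covariates (age, sex, chronic conditions, baseline depression), with
#' a participant random intercept. Maximum likelihood with adaptive
#' Gauss-Hermite quadrature (default 10 points; Laplace fallback on
#' failure). Rows with a missing outcome or predictor are dropped
#' (available case).
#'
#' @param rows Output of [assemble_daily_table()].
#' @param predictor One of the daily predictor names (see
#'   `DAILY_PREDICTORS`).
#' @param outcome `"same_day"` or `"next_day"`.
#' @param nAGQ Quadrature points (default 10).
#' @return One-row data frame: `predictor`, `outcome`, `odds_ratio`,
#'   `ci_low`, `ci_high`, `p_value`, `converged`, `n_obs`,
#'   `n_participants`, `note`.
#' @export
fit_daily_model <- function(rows, predictor, outcome = c("same_day", "next_day"),
                            nAGQ = 10) {
  outcome <- match.arg(outcome)
  xc <- paste0(predictor, "_c")
  if (!xc %in% names(rows)) stop("unknown predictor: ", predictor)
  y <- if (outcome == "same_day") rows$symptom_binary else rows$symptom_next_day
  d <- data.frame(y = y, x = rows[[xc]], age_gm = rows$age_gm,
                  sex_gm = rows$sex_gm, chronic_gm = rows$chronic_gm,
                  gds_gm = rows$gds_gm, pid = rows$participant_id)
  d <- d[stats::complete.cases(d), , drop = FALSE]
  tab <- table(d$pid)
  if (sum(tab >= 2L) < 2L) stop("need >= 2 participants with >= 2 days each")
  wvar <- tapply(d$x, d$pid, function(v) stats::var(v))
  if (all(is.na(wvar) | wvar < .Machine$double.eps)) {
    stop("degenerate predictor: no within-person variance in ", predictor)
  }

  notes <- character(0)
  fit <- NULL
  for (q in unique(c(nAGQ, 1))) {
    fit <- withCallingHandlers(
      tryCatch(lme4::glmer(y ~ x + age_gm + sex_gm + chronic_gm + gds_gm +
                             (1 | pid),
                           data = d, family = stats::binomial, nAGQ = q),
               error = function(e) {
                 notes <<- c(notes, conditionMessage(e))
                 NULL
               }),
      warning = function(w) {
        notes <<- c(notes, conditionMessage(w))
        invokeRestart("muffleWarning")
      },
      message = function(m) invokeRestart("muffleMessage"))
    if (!is.null(fit)) break
  }
  if (is.null(fit)) {
    return(data.frame(predictor = predictor, outcome = outcome,
                      odds_ratio = NA_real_, ci_low = NA_real_,
                      ci_high = NA_real_, p_value = NA_real_,
                      converged = FALSE, n_obs = nrow(d),
                      n_participants = length(tab),
                      note = paste(unique(notes), collapse = "; ")))
  }
  co <- suppressWarnings(summary(fit))$coefficients
  b <- co["x", "Estimate"]
  se <- co["x", "Std. Error"]
  z <- stats::qnorm(0.975)
  converged <- length(fit@optinfo$conv$lme4$messages) == 0 &&
    !any(grepl("failed to converge", notes))
  if (abs(b) > 15 || se > 10) {
    converged <- FALSE
    notes <- c(notes, "possible complete separation")
  }
  data.frame(predictor = predictor, outcome = outcome,
             odds_ratio = exp(b), ci_low = exp(b - z * se),
             ci_high = exp(b + z * se),
             p_value = 2 * stats::pnorm(-abs(b / se)),
             converged = converged, n_obs = nrow(d),
             n_participants = length(tab),
             note = paste(unique(notes), collapse = "; "))
}

#' Fit the full model battery (11 predictors x 2 outcomes)
#'
#' One model per daily predictor and outcome. Within each outcome family
#' of 11 tests, Holm's step-down correction at family alpha 0.05 flags
#' `significant_holm`; the fixed threshold `p < .005` flags
#' `significant_p005`.
#'
#' @param rows Output of [assemble_daily_table()].
#' @param nAGQ Passed to [fit_daily_model()].
#' @return Data frame of 22 model rows with significance flags.
#' @export
run_model_battery <- function(rows, nAGQ = 10) {
  res <- list()
  for (outc in c("same_day", "next_day")) {
    for (pred in DAILY_PREDICTORS) {
      r <- tryCatch(fit_daily_model(rows, pred, outc, nAGQ = nAGQ),
                    error = function(e) {
                      data.frame(predictor = pred, outcome = outc,
                                 odds_ratio = NA_real_, ci_low = NA_real_,
                                 ci_high = NA_real_, p_value = NA_real_,
                                 converged = FALSE, n_obs = 0L,
                                 n_participants = 0L,
                                 note = conditionMessage(e))
                    })
      res[[length(res) + 1L]] <- r
    }
  }
  out <- do.call(rbind, res)
  out$significant_holm <- FALSE
  for (outc in c("same_day", "next_day")) {
    sel <- out$outcome == outc & !is.na(out$p_value)
    if (any(sel)) {
      out$significant_holm[sel] <- holm_bonferroni(out$p_value[sel], alpha = 0.05)
    }
  }
  out$significant_p005 <- !is.na(out$p_value) & out$p_value < 0.005
  rownames(out) <- NULL
  out
}

#' Holm step-down multiple-testing flags
#'
#' Rejects the ordered hypotheses while `p_(i) <= alpha / (m - i + 1)`;
#' the returned flags are monotone (any rejection implies rejection of
#' all smaller p-values).
#'
#' @param p_values Numeric vector in [0, 1].
#' @param alpha Family-wise error rate (default 0.05).
#' @return Logical rejection flags, same order as the input.
#' @export
holm_bonferroni <- function(p_values, alpha = 0.05) {
  if (!length(p_values)) return(logical(0))
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "holm") <= alpha
}

#' Person-level bivariate correlations
#'
#' Pearson correlations among baseline depression, the person mean of
#' daily symptoms, and the person means of the daily digital markers,
#' pairwise complete. Cells with fewer than 3 complete pairs are `NA`.
#'
#' @param rows Output of [assemble_daily_table()].
#' @param profiles Participant table.
#' @return List with matrices `r`, `p`, `n` and the person-level table
#'   `person_means`.
#' @export
person_mean_correlations <- function(rows, profiles) {
  ids <- sort(unique(rows$participant_id))
  pm <- data.frame(participant_id = ids)
  pm$baseline_gds <- profiles$baseline_gds[match(ids, profiles$participant_id)]
  agg <- function(v) {
    as.numeric(tapply(rows[[v]], rows$participant_id, mean, na.rm = TRUE)[ids])
  }
  pm$p_symptom_days <- agg("symptom_binary")
  for (v in DAILY_PREDICTORS) pm[[v]] <- agg(v)
  vars <- setdiff(names(pm), "participant_id")
  k <- length(vars)
  r <- p <- n <- matrix(NA_real_, k, k, dimnames = list(vars, vars))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      x <- pm[[vars[i]]]; y <- pm[[vars[j]]]
      ok <- is.finite(x) & is.finite(y)
      n[i, j] <- sum(ok)
      if (i == j) {
        r[i, j] <- 1; p[i, j] <- 0
      } else if (sum(ok) >= 3L && stats::sd(x[ok]) > 0 && stats::sd(y[ok]) > 0) {
        ct <- stats::cor.test(x[ok], y[ok])
        r[i, j] <- unname(ct$estimate)
        p[i, j] <- ct$p.value
      }
    }
  }
  list(r = r, p = p, n = n, person_means = pm)
}
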