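# Day-level table assembly, multilevel models, multiplicity correction,
# correlations.

make_rows <- function(seed = 23L, n = 12L, days = 20L, ...) {
  coh <- apply_missingness(tiny_day_cohort(seed = seed, n = n, days = days, ...),
                           c(survey = 0.1, hrv = 0, sleep = 0.2, steps = 0))
  assemble_daily_table(coh$sleep_nights, coh$surveys, coh$profiles)
}

test_that("assembly links each day to the night ending that morning", {
  coh <- tiny_day_cohort(seed = 3L, n = 3L, days = 10L)
  rows <- assemble_daily_table(coh$sleep_nights, coh$surveys, coh$profiles,
                               skip_week1 = FALSE)
  sn <- coh$sleep_nights
  i <- which(!is.na(rows$sfi))[5]
  night <- sn[sn$participant_id == rows$participant_id[i] &
                sn$night_date == rows$date[i] - 1L, ]
  expect_equal(rows$sfi[i], 100 * night$sfi)
  expect_equal(rows$se[i], night$se)
  expect_equal(rows$tst[i], night$tst)
  # day 1 has no preceding night
  expect_true(all(is.na(rows$sfi[rows$date == min(rows$date)])))
  # last day's next-day outcome is missing
  for (pid in unique(rows$participant_id)) {
    sub <- rows[rows$participant_id == pid, ]
    expect_true(is.na(sub$symptom_next_day[which.max(sub$date)]))
    # interior next-day outcomes equal the following day's binary
    d <- sub$date[3]
    expect_equal(sub$symptom_next_day[sub$date == d],
                 sub$symptom_binary[sub$date == d + 1L])
  }
})

test_that("week-1 exclusion drops exactly the first 7 calendar days", {
  coh <- tiny_day_cohort(seed = 3L, n = 3L, days = 12L)
  all_rows <- assemble_daily_table(coh$sleep_nights, coh$surveys,
                                   coh$profiles, skip_week1 = FALSE)
  trimmed <- assemble_daily_table(coh$sleep_nights, coh$surveys,
                                  coh$profiles, skip_week1 = TRUE)
  expect_equal(nrow(all_rows) - nrow(trimmed), 3 * 7)
  expect_true(all(trimmed$date >= min(all_rows$date) + 7))
})

test_that("duplicate participant-date keys are rejected", {
  coh <- tiny_day_cohort(seed = 3L, n = 3L, days = 10L)
  expect_error(assemble_daily_table(coh$sleep_nights,
                                    rbind(coh$surveys, coh$surveys[1, ]),
                                    coh$profiles),
               "duplicate participant-date")
})

test_that("centered predictors average to zero within person", {
  rows <- make_rows()
  for (v in c("sfi_c", "se_c", "tst_c")) {
    wm <- tapply(rows[[v]], rows$participant_id, mean, na.rm = TRUE)
    expect_lt(max(abs(wm), na.rm = TRUE), 1e-9)
  }
  # covariates are grand-mean centered over participants
  first <- !duplicated(rows$participant_id)
  expect_lt(abs(mean(rows$age_gm[first])), 1e-9)
  expect_lt(abs(mean(rows$gds_gm[first])), 1e-9)
})

test_that("the model recovers a known coupling and reports Wald intervals", {
  coh <- tiny_day_cohort(seed = 52L, n = 25L, days = 33L)
  rows <- assemble_daily_table(coh$sleep_nights, coh$surveys, coh$profiles)
  f <- fit_daily_model(rows, "sfi", "same_day")
  expect_true(f$converged)
  expect_true(f$ci_low <= f$odds_ratio && f$odds_ratio <= f$ci_high)
  expect_gt(f$odds_ratio, 1) # true coupling is positive
  expect_equal(f$n_participants, 25)
  # Wald interval is symmetric on the log scale
  expect_equal(log(f$ci_high) - log(f$odds_ratio),
               log(f$odds_ratio) - log(f$ci_low), tolerance = 1e-6)
})

test_that("degenerate predictors raise an error rather than a silent fit", {
  rows <- make_rows(seed = 5L)
  rows$tst <- 300; rows$tst_c <- 0
  expect_error(fit_daily_model(rows, "tst", "same_day"),
               "degenerate predictor")
  expect_error(fit_daily_model(rows, "nope", "same_day"), "unknown predictor")
  few <- rows[rows$participant_id == rows$participant_id[1], ]
  expect_error(fit_daily_model(few, "sfi", "same_day"), ">= 2 participants")
})

test_that("the battery fits 11 predictors for both outcomes with flags", {
  coh <- tiny_day_cohort(seed = 52L, n = 15L, days = 25L)
  rows <- assemble_daily_table(coh$sleep_nights, coh$surveys, coh$profiles)
  bat <- run_model_battery(rows, nAGQ = 1)
  expect_equal(nrow(bat), 22)
  expect_equal(sort(unique(bat$outcome)), c("next_day", "same_day"))
  expect_equal(sum(bat$outcome == "same_day"), 11)
  # day-level cohorts carry no HRV/activity: those models fail loudly
  expect_true(all(!bat$converged[bat$predictor == "hf"]))
  expect_true(all(bat$note[bat$predictor == "hf"] != ""))
  # fixed-threshold flag matches p < .005
  ok <- !is.na(bat$p_value)
  expect_equal(bat$significant_p005[ok], bat$p_value[ok] < 0.005)
})

test_that("Holm step-down matches the hand calculation and is monotone", {
  # m = 11 family: smallest p against alpha/11, next against alpha/10
  p <- c(0.001, 0.003, rep(0.5, 9))
  flags <- holm_bonferroni(p, alpha = 0.05)
  expect_true(flags[1]) # 0.001 < 0.05/11 = 0.00455
  expect_true(flags[2]) # 0.003 < 0.05/10 = 0.005
  expect_false(any(flags[3:11]))
  expect_false(any(holm_bonferroni(rep(0.5, 8))))
  expect_equal(holm_bonferroni(numeric(0)), logical(0))
  expect_error(holm_bonferroni(c(0.5, 1.2)), "\\[0, 1\\]")
  # monotone: rejecting p_(i) implies rejecting all smaller p
  set.seed(8)
  for (r in 1:50) {
    p <- runif(11)^sample(1:4, 1)
    fl <- holm_bonferroni(p)
    if (any(fl)) expect_true(all(fl[p <= max(p[fl])]))
  }
})

test_that("person-mean correlations: self-correlation 1, coupling sign recovered", {
  coh <- tiny_day_cohort(seed = 62L, n = 40L, days = 30L)
  rows <- assemble_daily_table(coh$sleep_nights, coh$surveys, coh$profiles)
  pc <- person_mean_correlations(rows, coh$profiles)
  expect_true(all(diag(pc$r) == 1))
  expect_equal(pc$r, t(pc$r))
  # the generator couples habitual sleep efficiency negatively to the
  # person-level symptom propensity
  expect_lt(pc$r["p_symptom_days", "se"], 0)
  # baseline depression feeds the person intercept: positive correlation
  expect_gt(pc$r["p_symptom_days", "baseline_gds"], 0)
  # markers with no generated person-level coupling stay near zero:
  # hrv columns are absent at day level -> NA cells
  expect_true(is.na(pc$r["p_symptom_days", "hf"]))
})
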