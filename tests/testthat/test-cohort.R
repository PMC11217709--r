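# Synthetic cohort generator: dimensions, determinism, missingness, I/O.

test_that("cohort dimensions follow the configuration", {
  cfg <- sim_config(n_participants = 4L, n_days = 9L, seed = 2L, level = "day")
  coh <- generate_cohort(cfg)
  expect_equal(nrow(coh$profiles), 4)
  expect_equal(nrow(coh$surveys), 4 * 9)
  expect_equal(nrow(coh$sleep_nights), 4 * 8) # one night per day pair
  expect_true(all(coh$profiles$age >= 65))
  expect_true(all(coh$profiles$baseline_gds >= 0 & coh$profiles$baseline_gds <= 15))
  expect_true(all(coh$profiles$baseline_psqi >= 0 & coh$profiles$baseline_psqi <= 21))
  expect_equal(sum(coh$profiles$reversed_cycle), 1)
  # per-participant day counts
  cfg <- sim_config(n_participants = 3L, n_days = c(8L, 10L, 12L), seed = 2L,
                    level = "day")
  coh <- generate_cohort(cfg)
  expect_equal(as.integer(table(coh$surveys$participant_id)), c(8L, 10L, 12L))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_participants = 1L), "n_participants")
  expect_error(sim_config(n_days = 5L), "n_days")
  expect_error(sim_config(missing_rates = c(survey = 1.2, hrv = 0, sleep = 0,
                                            steps = 0)), "\\[0, 1\\]")
  expect_error(sim_config(missing_rates = c(survey = 0, hrv = 0, sleep = 0,
                                            steps = 0, voice = 0.5)),
               "unknown missingness domain")
})

test_that("identical config and seed give byte-identical written cohorts", {
  cfg <- sim_config(n_participants = 3L, n_days = 8L, seed = 31L)
  d1 <- file.path(tempdir(), "coh1"); d2 <- file.path(tempdir(), "coh2")
  write_cohort(apply_missingness(generate_cohort(cfg)), d1)
  write_cohort(apply_missingness(generate_cohort(cfg)), d2)
  for (f in c("participants.csv", "surveys.csv", "minutes.csv")) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  }
  # a different seed changes the stream
  cfg2 <- sim_config(n_participants = 3L, n_days = 8L, seed = 32L)
  d3 <- file.path(tempdir(), "coh3")
  write_cohort(generate_cohort(cfg2), d3)
  expect_false(identical(unname(tools::md5sum(file.path(d1, "surveys.csv"))),
                         unname(tools::md5sum(file.path(d3, "surveys.csv")))))
  unlink(c(d1, d2, d3), recursive = TRUE)
})

test_that("cohorts round-trip through the CSV interchange", {
  coh <- apply_missingness(generate_cohort(
    sim_config(n_participants = 3L, n_days = 8L, seed = 13L)))
  dir <- file.path(tempdir(), "rt")
  write_cohort(coh, dir)
  back <- read_cohort(dir)
  expect_equal(back$profiles$participant_id, coh$profiles$participant_id)
  expect_equal(back$profiles$baseline_gds, coh$profiles$baseline_gds)
  expect_equal(back$profiles$sus_pre, coh$profiles$sus_pre, tolerance = 1e-12)
  expect_equal(back$surveys$symptom_binary, coh$surveys$symptom_binary)
  expect_equal(back$surveys$date, coh$surveys$date)
  expect_equal(back$minutes$heart_rate, coh$minutes$heart_rate)
  expect_equal(back$minutes$sleep_class, coh$minutes$sleep_class)
  expect_equal(back$minutes$steps, coh$minutes$steps)
  expect_equal(back$minutes$minute, coh$minutes$minute)
  # blank cells, not sentinel numbers, for missing values
  raw <- readLines(file.path(dir, "surveys.csv"))
  expect_false(any(grepl("-999|NaN", raw)))
  unlink(dir, recursive = TRUE)
})

test_that("reading a missing directory names the path", {
  expect_error(read_cohort(file.path(tempdir(), "nope")),
               "missing input file.*participants.csv")
})

test_that("missingness masks exact per-domain day counts", {
  coh <- tiny_day_cohort(seed = 88L, n = 25L, days = 33L)
  n_days <- nrow(coh$surveys)
  n_nights <- nrow(coh$sleep_nights)
  rates <- c(survey = 0.23, hrv = 0.333, sleep = 0.545, steps = 0.369)
  m <- apply_missingness(coh, rates)
  expect_equal(sum(is.na(m$surveys$symptom_binary)), round(0.23 * n_days))
  expect_equal(sum(!m$sleep_nights$valid), round(0.545 * n_nights))
  expect_equal(nrow(m$missing_assignments$hrv), round(0.333 * n_days))
  expect_equal(nrow(m$missing_assignments$steps), round(0.369 * n_days))
  # zero rates: identity
  m0 <- apply_missingness(coh, c(survey = 0, hrv = 0, sleep = 0, steps = 0))
  expect_equal(m0$surveys, coh$surveys)
  expect_equal(m0$sleep_nights, coh$sleep_nights)
  # rate 1: every night lacks sleep metrics downstream
  m1 <- apply_missingness(coh, c(survey = 0, hrv = 0, sleep = 1, steps = 0))
  expect_true(all(!m1$sleep_nights$valid))
  rows <- assemble_daily_table(m1$sleep_nights, m1$surveys, m1$profiles)
  expect_true(all(is.na(rows$sfi)))
  expect_error(apply_missingness(coh, c(voice = 0.5)), "unknown missingness")
})

test_that("minute streams satisfy their invariants", {
  coh <- generate_cohort(sim_config(n_participants = 3L, n_days = 8L,
                                    seed = 61L))
  m <- coh$minutes
  expect_true(all(m$heart_rate >= 20 & m$heart_rate <= 220, na.rm = TRUE))
  expect_true(all(m$steps >= 0, na.rm = TRUE))
  # strictly increasing 1-minute timestamps per participant
  for (pid in unique(m$participant_id)) {
    sub <- m[m$participant_id == pid, ]
    key <- as.numeric(sub$date) * 1440 + sub$minute
    expect_true(all(diff(key) == 1))
  }
  expect_equal(nrow(m), 3 * 8 * 1440)
})

test_that("a null-coupling generator shows no within-person sleep effect", {
  coh <- generate_cohort(sim_config(n_participants = 20L, n_days = 33L,
                                    seed = 71L, beta_sfi = 0, beta_se = 0,
                                    level = "day"))
  rows <- assemble_daily_table(coh$sleep_nights, coh$surveys, coh$profiles)
  f <- fit_daily_model(rows, "sfi", "same_day")
  # under the null the Wald z is far from extreme
  z <- abs(log(f$odds_ratio)) / ((log(f$ci_high) - log(f$ci_low)) / (2 * 1.96))
  expect_lt(z, 4)
})

test_that("scored sleep on the cohort tracks the generator's parameters", {
  coh <- tiny_day_cohort(seed = 19L, n = 30L, days = 25L)
  sn <- coh$sleep_nights
  expect_gt(mean(sn$valid), 0.95)
  expect_lt(abs(mean(sn$tst) - 320), 45)
  expect_lt(abs(mean(sn$sfi) - 0.02), 0.012)
  expect_true(mean(sn$se) > 55 && mean(sn$se) < 90)
})
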