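# Nightly sleep scoring: rescoring rules, onset/offset, metrics.

W <- 0L; S <- 1L

test_that("rescoring rules reproduce their defining cases", {
  # 10 awake then 5 asleep: first 3 sleep minutes become awake
  x <- c(rep(W, 10), rep(S, 5))
  expect_equal(rescore_sleep(x), c(rep(W, 13), S, S))
  # 5-minute sleep bout flanked by 16 awake minutes both sides is removed
  x <- c(rep(W, 16), rep(S, 5), rep(W, 16))
  expect_equal(rescore_sleep(x), rep(W, 37))
  # 15-minute flanks are not "more than 15": the isolated-bout stage
  # leaves the bout alone (tested on the stage directly, since rule 2
  # legitimately trims the first 3 minutes after a 15-minute awake run)
  x <- c(rep(W, 15), rep(S, 5), rep(W, 15))
  expect_equal(wearlab:::.rescore_isolated(x, 5L, 16L), x)
  # 9-minute sleep bout with 21 awake both sides is removed (rule 5)
  x <- c(rep(W, 21), rep(S, 9), rep(W, 21))
  expect_equal(rescore_sleep(x), rep(W, 51))
  # all-asleep series unchanged
  expect_equal(rescore_sleep(rep(S, 30)), rep(S, 30))
})

test_that("criterion 1 direction: printed keeps sleep, webster rescores to wake", {
  x <- c(rep(W, 4), rep(S, 12))
  expect_equal(rescore_sleep(x, "as_printed"), x)
  web <- rescore_sleep(x, "webster")
  expect_equal(web[5], W)
  expect_equal(web[6:16], rep(S, 11))
})

test_that("rescoring matches the literal-scan oracle exhaustively (length <= 14)", {
  for (len in 1:14) {
    shifts <- 0:(len - 1)
    for (dir in c("as_printed", "webster")) {
      ok <- vapply(0:(2^len - 1), function(p) {
        x <- as.integer(bitwAnd(bitwShiftR(p, shifts), 1L))
        identical(rescore_sleep(x, dir), oracle_rescore(x, dir))
      }, logical(1))
      expect_true(all(ok), info = paste("length", len, dir))
    }
  }
})

test_that("rescoring matches the oracle on random long sequences with gaps", {
  set.seed(1407)
  for (r in 1:400) {
    len <- sample(15:22, 1)
    x <- random_sleep_seq(len, p_sleep = runif(1, 0.2, 0.8),
                          p_na = sample(c(0, 0.1), 1))
    dir <- sample(c("as_printed", "webster"), 1)
    expect_identical(rescore_sleep(x, dir), oracle_rescore(x, dir))
  }
  # longer sequences so the isolated-bout rules (3)-(5) actually fire
  for (r in 1:400) {
    x <- random_sleep_seq(60, p_sleep = runif(1, 0.15, 0.6),
                          p_na = sample(c(0, 0.05), 1))
    dir <- sample(c("as_printed", "webster"), 1)
    expect_identical(rescore_sleep(x, dir), oracle_rescore(x, dir))
  }
})

test_that("isolated-bout stages are idempotent; the full rescore has a
           documented rule-2 cascade counterexample", {
  iso <- function(x) wearlab:::.rescore_isolated(
    wearlab:::.rescore_isolated(x, 5L, 16L), 9L, 21L)
  set.seed(2024)
  for (r in 1:200) {
    x <- random_sleep_seq(80, p_sleep = runif(1, 0.2, 0.8))
    once <- iso(x)
    expect_identical(iso(once), once)
  }
  # rule 2 extends awake runs, so a second pass can convert further sleep
  x <- c(rep(W, 10), rep(S, 6))
  once <- rescore_sleep(x)
  expect_false(identical(rescore_sleep(once), once))
})

test_that("rescoring never increases total sleep time", {
  set.seed(99)
  for (r in 1:200) {
    x <- random_sleep_seq(90, p_sleep = runif(1, 0.2, 0.9))
    for (dir in c("as_printed", "webster")) {
      expect_lte(sum(rescore_sleep(x, dir) == S),
                 sum(x == S))
    }
  }
})

test_that("onset/offset detection follows the 10-minute run definition", {
  x <- rep(W, 300)
  x[101:110] <- S
  oo <- detect_onset_offset(x)
  expect_equal(oo$onset, 101)
  expect_equal(oo$offset, 110)
  expect_true(oo$valid)
  # 9-minute runs never qualify
  x <- rep(c(rep(S, 9), W), 10)
  expect_false(detect_onset_offset(x)$valid)
  # first run start, last run end
  x <- c(rep(W, 5), rep(S, 12), rep(W, 40), rep(S, 15), rep(W, 3))
  oo <- detect_onset_offset(x)
  expect_equal(oo$onset, 6)
  expect_equal(oo$offset, 72)
  # missing minutes break runs: two 9-minute fragments never qualify
  x <- rep(S, 19); x[10] <- NA
  expect_false(detect_onset_offset(x)$valid)
})

test_that("sleep metrics follow the printed formulas", {
  # 400 minutes in bed, 320 asleep -> SE 80%
  x <- c(rep(S, 160), rep(W, 80), rep(S, 160))
  m <- sleep_metrics(x, onset = 1L, offset = 400L)
  expect_equal(m$time_in_bed, 400)
  expect_equal(m$tst, 320)
  expect_equal(m$se, 80)
  # TST 300 with exactly 3 awakenings > 1 minute -> SFI 0.01
  x <- c(rep(S, 100), W, W, rep(S, 100), rep(W, 3), rep(S, 50), W,
         rep(S, 24), W, W, rep(S, 26)) # the 1-minute awakening not counted
  oo <- detect_onset_offset(x)
  m <- sleep_metrics(x, oo$onset, oo$offset)
  expect_equal(m$n_awakenings, 3)
  expect_equal(m$tst, 300)
  expect_equal(m$sfi, 0.01)
  # uninterrupted sleep: SFI 0, SE 100
  m <- sleep_metrics(rep(S, 200), onset = 1L, offset = 200L)
  expect_equal(m$sfi, 0)
  expect_equal(m$se, 100)
  expect_equal(m$n_awakenings, 0)
})

test_that("metrics agree with a brute-force oracle on random nights", {
  set.seed(314)
  for (r in 1:150) {
    x <- random_sleep_seq(400, p_sleep = runif(1, 0.5, 0.95),
                          p_na = sample(c(0, 0.03), 1))
    x <- rescore_sleep(x)
    oo <- detect_onset_offset(x)
    oo2 <- oracle_onset_offset(x)
    expect_identical(oo[c("onset", "offset", "valid")],
                     oo2[c("onset", "offset", "valid")])
    if (oo$valid) {
      m <- sleep_metrics(x, oo$onset, oo$offset)
      o <- oracle_sleep_metrics(x, oo$onset, oo$offset)
      expect_equal(m$tst, o$tst)
      expect_equal(m$n_awakenings, o$n_awakenings)
      expect_equal(m$n_long_episodes, o$n_long)
      expect_equal(m$sfi, o$sfi)
      expect_equal(m$se, o$se)
    }
  }
})

test_that("window extraction covers 6 PM to noon, or the reversed daytime window", {
  days <- as.Date("2023-03-06") + 0:2
  minutes <- data.frame(
    participant_id = "P01",
    date = rep(days, each = 1440L),
    minute = rep(0:1439, 3),
    sleep_class = 0L)
  # mark 23:00-23:59 of day 1 asleep
  minutes$sleep_class[minutes$date == days[1] & minutes$minute >= 1380] <- 1L
  win <- extract_sleep_window(minutes, days[1])
  expect_length(win$classes, 1080)
  expect_equal(sum(win$classes == 1L, na.rm = TRUE), 60)
  expect_equal(which(win$classes == 1L)[1], 301) # 23:00 is minute 301 of window
  # reversed window lies in [06:00, 24:00) of the following day
  minutes$sleep_class[minutes$date == days[2] & minutes$minute %in% 600:659] <- 1L
  rev <- extract_sleep_window(minutes, days[1], reversed_cycle = TRUE)
  expect_length(rev$classes, 1080)
  expect_equal(which(rev$classes == 1L)[1], 241) # 10:00 = window minute 241
  # absent coverage yields an all-missing window and invalid metrics
  empty <- extract_sleep_window(minutes[0, ], days[1])
  expect_true(all(is.na(empty$classes)))
  expect_false(sleep_metrics(empty)$valid)
})

test_that("nights with excessive missingness are flagged invalid", {
  x <- rep(S, 100)
  x[30:55] <- NA # 26% missing inside span
  # runs are broken by the gap but both flanks have >= 10 sleep minutes
  m <- sleep_metrics(x)
  expect_false(m$valid)
  expect_gt(m$pct_missing, 20)
  x[30:55] <- S
  x[40:45] <- NA # 6% missing: valid
  expect_true(sleep_metrics(x)$valid)
})

test_that("timestamps map window minutes to local clock time", {
  expect_equal(window_minute_to_timestamp(as.Date("2023-03-06"), 1L),
               "2023-03-06T18:00")
  expect_equal(window_minute_to_timestamp(as.Date("2023-03-06"), 361L),
               "2023-03-07T00:00")
  expect_equal(window_minute_to_timestamp(as.Date("2023-03-06"), 1080L),
               "2023-03-07T11:59")
  expect_equal(window_minute_to_timestamp(as.Date("2023-03-06"), 241L,
                                          reversed_cycle = TRUE),
               "2023-03-07T10:00")
})
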