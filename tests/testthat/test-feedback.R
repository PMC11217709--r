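# Traffic-light feedback bands and emergency alerts.

test_that("first-week baselines use sample SD over week-1 days", {
  daily <- data.frame(participant_id = "P01",
                      date = as.Date("2023-03-06") + 0:2,
                      domain = "steps", value = c(3000, 3200, 2800))
  b <- compute_baseline(daily)
  expect_equal(b$mean, 3000)
  expect_equal(b$sd, 200)
  expect_true(b$valid)
  # single non-missing day: invalid baseline
  b1 <- compute_baseline(daily[1, ])
  expect_false(b1$valid)
  # only week-1 days enter: a large week-2 value is ignored
  daily2 <- rbind(daily, data.frame(participant_id = "P01",
                                    date = as.Date("2023-03-06") + 10,
                                    domain = "steps", value = 99999))
  expect_equal(compute_baseline(daily2)$mean, 3000)
})

test_that("classification follows the +-1 SD bands with yellow boundaries", {
  expect_equal(classify_day(3000 + 1.5 * 200, 3000, 200, "steps"), "green")
  expect_equal(classify_day(3000 - 1.5 * 200, 3000, 200, "steps"), "red")
  expect_equal(classify_day(3000, 3000, 200, "steps"), "yellow")
  # boundaries inclusive to yellow
  expect_equal(classify_day(3200, 3000, 200, "steps"), "yellow")
  expect_equal(classify_day(2800, 3000, 200, "steps"), "yellow")
  # sleep fragmentation is inverted: higher is worse
  expect_equal(classify_day(0.05, 0.02, 0.01, "sleep_sfi"), "red")
  expect_equal(classify_day(0.005, 0.02, 0.01, "sleep_sfi"), "green")
  expect_equal(classify_day(0.02, 0.02, 0.01, "sleep_sfi"), "yellow")
  # missing value or invalid baseline: gray
  expect_equal(classify_day(NA, 3000, 200, "steps"), "gray")
  expect_equal(classify_day(3000, 3000, 200, "steps", valid = FALSE), "gray")
  # degenerate sd-zero baseline: any deviation leaves yellow
  expect_equal(classify_day(3001, 3000, 0, "steps"), "green")
  expect_equal(classify_day(2999, 3000, 0, "steps"), "red")
  expect_equal(classify_day(3000, 3000, 0, "steps"), "yellow")
})

test_that("the three bands tile the line and are monotone (antitone for sleep)", {
  grid <- seq(-4, 4, by = 0.05)
  for (dom in c("steps", "stress_hf", "activity", "sleep_sfi")) {
    cols <- vapply(grid, classify_day, character(1),
                   mean = 0, sd = 1, domain = dom)
    expect_true(all(cols %in% c("green", "yellow", "red")))
    ranks <- c(red = 1, yellow = 2, green = 3)[cols]
    if (dom == "sleep_sfi") ranks <- rev(ranks)
    expect_true(all(diff(ranks) >= 0))
  }
})

test_that("emergency triggers are strict inequalities at the printed thresholds", {
  base <- data.frame(participant_id = "P01", date = as.Date("2023-03-06"),
                     minute = 0:1439, heart_rate = 70,
                     steps = rep(c(0, 5), 720),
                     intensity = "sedentary")
  expect_equal(nrow(detect_emergencies(base)), 0)
  # single minute below 30 bpm
  m <- base; m$heart_rate[600] <- 25
  al <- detect_emergencies(m)
  expect_equal(al$trigger, "hr_low")
  expect_equal(al$timestamp, "2023-03-06T09:59") # row 600 is minute 599
  expect_equal(al$value, 25)
  # 140 exactly is not "rose above 140"; 141 is
  m <- base; m$heart_rate[10] <- 140
  expect_equal(nrow(detect_emergencies(m)), 0)
  m$heart_rate[10] <- 141
  expect_equal(detect_emergencies(m)$trigger, "hr_high")
  # 30 exactly does not trigger hr_low
  m <- base; m$heart_rate[10] <- 30
  expect_equal(nrow(detect_emergencies(m)), 0)
  # inactivity: 481 consecutive inactive minutes trigger, 480 do not
  m <- base
  m$steps <- c(rep(0, 480), rep(5, 960))
  expect_equal(nrow(detect_emergencies(m)), 0)
  m$steps <- c(rep(0, 481), rep(5, 959))
  al <- detect_emergencies(m)
  expect_equal(al$trigger, "inactivity_gt_8h")
  expect_equal(al$timestamp, "2023-03-06T08:00") # minute 480, first crossing
  # non-sedentary intensity breaks an inactive run even without steps
  m$intensity[240] <- "light"
  expect_equal(nrow(detect_emergencies(m)), 0)
})

test_that("default synthetic cohorts emit no emergency alerts", {
  coh <- generate_cohort(sim_config(n_participants = 4L, n_days = 8L,
                                    seed = 909L))
  expect_equal(nrow(detect_emergencies(coh$minutes)), 0)
})

test_that("feedback cards assign one color per domain per day", {
  coh <- generate_cohort(sim_config(n_participants = 2L, n_days = 10L,
                                    seed = 55L))
  act <- activity_daily(coh$minutes)
  hrvd <- data.frame(participant_id = act$participant_id, date = act$date,
                     mean_sdnn = 20, mean_rmssd = 5,
                     mean_hf = rnorm(nrow(act), 10, 3), mean_lf_hf = 4,
                     n_valid_windows = 288)
  fb <- feedback_cards(hrvd, coh$sleep_nights, act)
  cards <- fb$cards
  for (dom in c("stress_hf", "sleep_sfi", "steps", "activity")) {
    col <- cards[[paste0(dom, "_color")]]
    expect_true(all(col %in% c("green", "yellow", "red", "gray")))
    # gray exactly when the value is missing or the baseline invalid
    val <- cards[[paste0(dom, "_value")]]
    base <- fb$baselines[fb$baselines$domain == dom, ]
    bv <- base$valid[match(cards$participant_id, base$participant_id)]
    expect_equal(col == "gray", is.na(val) | !bv)
  }
})
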