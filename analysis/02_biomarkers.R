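#!/usr/bin/env Rscript
# Stage 2: derive the daily digital biomarkers from the minute streams.
#
# Scores every night (6 PM - noon window, rescoring criteria, onset and
# offset, TST / fragmentation index / efficiency), computes 5-minute
# HRV windows around the clock with daily summaries, and aggregates
# daily steps and intensity minutes. Nightly and daily tables go under
# results/.

library(wearlab)

cohort <- readRDS("scratch/cohort/cohort.rds")

sleep_nights <- score_sleep_nights(cohort$minutes, cohort$profiles)
utils::write.csv(sleep_nights, "results/sleep_nights.csv",
                 row.names = FALSE, na = "")
ok <- sleep_nights$valid
cat(sprintf("nights scored: %d, valid %d (%.1f%%)\n", nrow(sleep_nights),
            sum(ok), 100 * mean(ok)))
cat(sprintf("TST %.1f min, SFI %.3f, SE %.1f%% over valid nights\n",
            mean(sleep_nights$tst[ok]), mean(sleep_nights$sfi[ok]),
            mean(sleep_nights$se[ok])))

windows <- hrv_windows(cohort$minutes)
utils::write.csv(windows, "scratch/hrv_windows.csv", row.names = FALSE, na = "")
hrv_day <- hrv_daily(windows)
utils::write.csv(hrv_day, "results/hrv_daily.csv", row.names = FALSE, na = "")
cat(sprintf("HRV: %d windows, %d participant-days with valid summaries\n",
            nrow(windows), nrow(hrv_day)))

act_day <- activity_daily(cohort$minutes)
utils::write.csv(act_day, "results/activity_daily.csv",
                 row.names = FALSE, na = "")
cat(sprintf("activity: mean %.0f steps, %.0f light / %.0f moderate / %.0f intense min\n",
            mean(act_day$steps, na.rm = TRUE),
            mean(act_day$light_min, na.rm = TRUE),
            mean(act_day$moderate_min, na.rm = TRUE),
            mean(act_day$intense_min, na.rm = TRUE)))
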