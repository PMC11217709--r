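#!/usr/bin/env Rscript
# Stage 4: day-level multilevel models.
#
# Assembles the analysis table (previous-night sleep metrics, daily HRV
# and activity summaries, same-day and next-day symptom binaries;
# adaptation week excluded; person-mean-centered level-1 predictors,
# grand-mean-centered level-2 covariates), fits the 22-model battery
# (11 predictors x same-day / next-day) with Holm and fixed-threshold
# significance flags, and the person-level correlation matrix.

library(wearlab)

cohort <- readRDS("scratch/cohort/cohort.rds")
sleep_nights <- utils::read.csv("results/sleep_nights.csv")
sleep_nights$night_date <- as.Date(sleep_nights$night_date)
hrv_day <- utils::read.csv("results/hrv_daily.csv")
hrv_day$date <- as.Date(hrv_day$date)
act_day <- utils::read.csv("results/activity_daily.csv")
act_day$date <- as.Date(act_day$date)

rows <- assemble_daily_table(sleep_nights, cohort$surveys, cohort$profiles,
                             hrv_day = hrv_day, act_day = act_day,
                             skip_week1 = TRUE)
utils::write.csv(rows, "results/daily_rows.csv", row.names = FALSE, na = "")
cat(sprintf("analysis table: %d participant-days after week-1 exclusion\n",
            nrow(rows)))

battery <- run_model_battery(rows)
utils::write.csv(battery, "results/model_results.csv",
                 row.names = FALSE, na = "")
same <- battery[battery$outcome == "same_day", ]
cat("\nsame-day models (OR per unit person-centered predictor):\n")
print(same[, c("predictor", "odds_ratio", "ci_low", "ci_high", "p_value",
               "significant_holm", "significant_p005")], digits = 3,
      row.names = FALSE)
cat("\nsleep rows, next-day models:\n")
nxt <- battery[battery$outcome == "next_day" &
                 battery$predictor %in% c("tst", "sfi", "se"), ]
print(nxt[, c("predictor", "odds_ratio", "ci_low", "ci_high", "p_value")],
      digits = 3, row.names = FALSE)

pc <- person_mean_correlations(rows, cohort$profiles)
utils::write.csv(round(pc$r, 3), "results/person_correlations.csv", na = "")
cat(sprintf("\nperson-level r(symptom days, sleep efficiency) = %.2f\n",
            pc$r["p_symptom_days", "se"]))
cat(sprintf("person-level r(symptom days, baseline GDS) = %.2f\n",
            pc$r["p_symptom_days", "baseline_gds"]))
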