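#!/usr/bin/env Rscript
# Stage 5: pre/post outcomes and baseline group descriptives.
#
# Exact Wilcoxon signed-rank tests for depression (GDS) and sleep
# quality (PSQI) change, paired t for usability (SUS), the 2 x 2 mixed
# ANOVA for age moderation of usability, and the depressed vs
# non-depressed (GDS >= 5) group comparison table.

library(wearlab)

cohort <- readRDS("scratch/cohort/cohort.rds")
prof <- cohort$profiles

pp <- pre_post_tests(prof)
fmt <- function(name, x) {
  cat(sprintf("%-22s W = %6.1f  z = %6.3f  p = %.3f  median diff %.1f (%.1f, %.1f)\n",
              name, x$statistic, x$z, x$p_value, x$median_diff,
              x$ci_low, x$ci_high))
}
fmt("GDS (depression)", pp$gds)
fmt("PSQI (sleep quality)", pp$psqi)
cat(sprintf("%-22s t(%d) = %.3f  p = %.3f  mean diff %.2f (%.2f, %.2f)\n",
            "SUS (usability)", pp$sus$df, pp$sus$statistic, pp$sus$p_value,
            pp$sus$mean_diff, pp$sus$ci_low, pp$sus$ci_high))
cat(sprintf("%-22s F(%d,%d) = %.2f  p = %.3f\n", "SUS age moderation",
            pp$sus_age_moderation$df1, pp$sus_age_moderation$df2,
            pp$sus_age_moderation$F, pp$sus_age_moderation$p_value))

res <- data.frame(
  outcome = c("gds", "psqi", "sus"),
  statistic = c(pp$gds$statistic, pp$psqi$statistic, pp$sus$statistic),
  p_value = c(pp$gds$p_value, pp$psqi$p_value, pp$sus$p_value))
utils::write.csv(res, "results/prepost_tests.csv", row.names = FALSE, na = "")

tab <- descriptive_table(prof)
utils::write.csv(tab, "results/descriptives.csv", row.names = FALSE, na = "")
cat("\nbaseline comparison (GDS >= 5 vs < 5):\n")
print(tab, digits = 3, row.names = FALSE)
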