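#!/usr/bin/env Rscript
# Stage 3: the statistical battery over the stage-2 wedge table: one-way
# ANOVA across the six conditions, Tukey HSD for all 15 pairs, and Pearson
# correlations of wedge width with bone lengths.
# Usage: Rscript analysis/03_statistics.R

library(owhtoplan)

cohort <- read_cohort_csv("results/cohort.csv")
wedges <- read.csv("results/wedges.csv")
wedges$error <- NA_character_

groups <- split(wedges$wedge_mm, wedges$condition)
an <- anova_oneway(groups)
cat(sprintf("one-way ANOVA across the six conditions: F(%d, %d) = %.3f, p = %.3f\n",
            an$df_between, an$df_within, an$statistic, an$p_value))

tk <- tukey_hsd(groups)
tk$significant <- ifelse(tk$p_adj < 0.05, "*", "")
write.csv(tk, "results/tukey.csv", row.names = FALSE)
cat("\nTukey HSD (mm):\n")
print(transform(tk, diff = round(diff, 3), lwr = round(lwr, 2),
                upr = round(upr, 2), p_adj = round(p_adj, 3)),
      row.names = FALSE)

lc <- length_correlations(wedges, cohort)
write.csv(lc, "results/correlations.csv", row.names = FALSE)
cat(sprintf("\nwedge vs bone length: |r| <= %.2f over all conditions (no correlation)\n",
            max(abs(lc$r))))
cat("wrote results/tukey.csv, results/correlations.csv\n")
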