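#!/usr/bin/env Rscript
# Stage 1: generate the default 55-knee varus cohort (printed case mix,
# truncated-normal geometry) and persist it for the later stages.
# Usage: Rscript analysis/01_simulate_cohort.R [--seed <int>]

library(owhtoplan)
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(i <- which(args == "--seed"))) as.integer(args[i + 1]) else 1L

dir.create("results", showWarnings = FALSE)
cohort <- generate_cohort(cohort_spec(), seed = seed)
write_cohort_csv(cohort, "results/cohort.csv")

cat(sprintf("cohort: %d knees (%d right / %d left), seed %d\n",
            nrow(cohort), sum(cohort$side == "right"),
            sum(cohort$side == "left"), seed))
cat(sprintf("mean varus %.2f deg (range %g-%g), mean plateau %.1f mm, femur %.1f mm, tibia %.1f mm\n",
            mean(cohort$varus_deg), min(cohort$varus_deg),
            max(cohort$varus_deg), mean(cohort$plateau_width_mm),
            mean(cohort$femoral_length_mm), mean(cohort$tibial_length_mm)))
cat("wrote results/cohort.csv\n")
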