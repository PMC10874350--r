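#!/usr/bin/env Rscript

# Step 2: run the full analysis on a cohort directory: ingest event logs,
# score the ULS-8 questionnaire, apply the 3-of-4 complete-weeks filter,
# build five-bin diurnal profiles, and run the group-level statistics
# (per-bin ANOVAs + Tukey, quadratic-coefficient ANOVA, weekday/weekend
# cosine-similarity Welch tests). Tables land in results/analysis/.
#
# Usage: Rscript analysis/02_run_analysis.R [cohort_dir] [out_dir]

suppressPackageStartupMessages(library(lonelykeys))

args <- commandArgs(trailingOnly = TRUE)
cohort_dir <- if (length(args) >= 1) args[1] else "scratch/cohort"
out <- if (length(args) >= 2) args[2] else "results/analysis"

report <- run_analysis(file.path(cohort_dir, "events"),
                       file.path(cohort_dir, "uls8.csv"),
                       file.path(cohort_dir, "calendar.yaml"),
                       output_dir = out)
print(report)
cat("Report tables written to", out, "\n")
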