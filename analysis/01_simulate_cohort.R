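#!/usr/bin/env Rscript

# Step 1: simulate one synthetic study cohort under the shipped
# study-condition profiles (59 participants in groups 18/26/10/5, five
# study weeks, ~4,500 keystrokes/day) and write it in the pipeline's
# input formats. The cohort directory is large (millions of events), so
# it goes under scratch/.
#
# Usage: Rscript analysis/01_simulate_cohort.R [seed] [out_dir]

suppressPackageStartupMessages(library(lonelykeys))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[1]) else 101L
out <- if (length(args) >= 2) args[2] else "scratch/cohort"

cfg <- sim_cohort_config(seed = seed)
cat("Generating cohort (seed", seed, ")...\n")
cohort <- generate_cohort(cfg, events = TRUE)

n_events <- sum(vapply(cohort$events,
                       function(l) if (is.null(l)) 0L else nrow(l$events), 0L))
groups <- vapply(cohort$ground_truth, function(t) t$group, "")
cat(sprintf("  %d participants (%s), %.1fM keystroke events\n",
            length(groups),
            paste(names(table(groups)), table(groups), sep = "=",
                  collapse = ", "),
            n_events / 1e6))

write_cohort(cohort, out)
cat("Cohort written to", out, "\n")
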