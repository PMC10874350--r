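# lonelykeys

Diurnal smartphone keystroke profiles and loneliness: an analysis
pipeline for digital-phenotyping studies that link the 8-item UCLA
Loneliness Scale (ULS-8) to *when* people type on their phones, using
only press/release timestamps (no key content).

## The analysis

Participants carry a logging keyboard for five study weeks (the first
week is an adjustment period and is discarded). For each participant the
pipeline:

1. **Bins keystrokes by clock time** into five sections tiling the day —
   sleep 00:00–06:00, morning 06:00–12:00, afternoon 12:00–17:00,
   evening 17:00–21:00, night 21:00–24:00 — counting each keystroke at
   its press timestamp.
2. **Filters by completeness**: a study week is complete when all 7 days
   have at least one keystroke; a participant is retained only with ≥ 3
   complete weeks out of the 4 analysis weeks.
3. **Builds diurnal profiles**: per-day bin counts `c = (c_1..c_5)` and
   count ratios `r_j = c_j / Σ c`, averaged over the retained days into a
   mean count profile and mean ratio profile, plus weekday-only and
   weekend-only ratio profiles (weekend = Saturday/Sunday).
4. **Scores the ULS-8** (items 1–6 as answered, items 7–8 reverse-coded
   as `5 − answer`; total 8–32) and assigns the four loneliness groups:
   *no* 8–13, *moderate* 14–20, *severe* 21–25, *very severe* 26–32.
5. **Runs the group statistics**:
   - one-way ANOVA of mean typing counts across the four groups, per
     time section, with Tukey–Kramer post-hoc pairs;
   - an OLS quadratic fit `y = a₂x² + a₁x + a₀` to each participant's
     five-bin mean count profile (x = bin index 1..5); the sign of `a₂`
     separates evening-peaked (concave, `a₂ < 0`) from late-night,
     U-shaped (convex, `a₂ > 0`) typing patterns; ANOVA on `a₂`;
   - cosine similarity `cos(u, v) = u·v / (‖u‖‖v‖)` between each
     participant's weekday and weekend mean ratio profiles, compared
     between groups with Welch's t-test (very-severe vs no loneliness is
     the headline pair).

Because cohorts of this kind are rarely shareable, the package ships a
synthetic-cohort generator: per-bin inhomogeneous Poisson keystroke
streams with group-conditional diurnal shapes (evening-peaked for the
lower-loneliness groups, night+sleep-peaked for the very-severe group),
weekday/weekend modulation, a lognormal per-participant activity
multiplier, day-level dropout, and banded ULS-8 responses. Every draw is
recorded as ground truth, so the whole pipeline is testable end to end.

## Worked example

```r
library(lonelykeys)
cfg <- sim_cohort_config(seed = 42)                 # 59 participants, 18/26/10/5
cohort <- generate_cohort(cfg, events = FALSE)      # counts-only fast path
report <- analyze_daily_counts(cohort$daily_counts, cohort$uls8, cfg$calendar)
print(report)
```

```
Diurnal keystroke / loneliness analysis
  included participants: 49 of 59
  group summary:
    no           n = 16  ULS-8 12.12 (1.09)  keystrokes 114755 (60356)
    moderate     n = 21  ULS-8 18.57 (1.91)  keystrokes 122784 (70597)
    severe       n =  8  ULS-8 22.00 (1.31)  keystrokes 95790 (59466)
    very_severe  n =  4  ULS-8 26.00 (0.00)  keystrokes 130971 (146187)
  sleep     typing-count ANOVA: F(3, 45) = 12.58, p = 0.0000 *
  morning   typing-count ANOVA: F(3, 45) = 1.47, p = 0.2352
  afternoon typing-count ANOVA: F(3, 45) = 0.55, p = 0.6487
  evening   typing-count ANOVA: F(3, 45) = 1.02, p = 0.3949
  night     typing-count ANOVA: F(3, 45) = 0.60, p = 0.6199
  quadratic coefficient ANOVA: F(3, 45) = 19.30, p = 0.0000 *
  cosine similarity, very_severe vs no: Welch t = 106.39, df = 15.1, p = 0.0000 *
```

Reading the output: 10 of the 59 simulated participants lost enough days
to fail the 3-complete-weeks rule. Only the sleep-time section separates
the groups (the very-severe group types heavily between midnight and
6 AM), the very-severe group's convex profiles give it a positive mean
quadratic coefficient against the negative means of the less lonely
groups, and its weekday/weekend ratio profiles are more similar than
those of the no-loneliness group (positive Welch t). The large F and t
values reflect the generator's clean Poisson noise; real keystroke data
carries far more behavioral variance.

## The analysis workflow

Numbered drivers under `analysis/` run the full study end to end:

```sh
Rscript analysis/01_simulate_cohort.R 101 scratch/cohort   # write a cohort (~0.4 GB)
Rscript analysis/02_run_analysis.R scratch/cohort results/analysis
Rscript analysis/03_replication_study.R 2024 500 100
```

`02` ingests the event-log files, applies every stage above, and writes
the report tables (inclusion decisions, profiles, ANOVA/Tukey tables,
quadratic coefficients, similarity scores, Welch pairs) under
`results/analysis/`. `03` runs the replicated calibration and
direction-recovery experiments and tabulates them under
`results/simstudy/`.

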