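---
title: "Diurnal typing profiles and loneliness: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diurnal typing profiles and loneliness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lonelykeys)
```

## The scientific question

Loneliness is associated with disturbed daily rhythms — late chronotypes,
night-time activity, and weekend routines that do not differ from weekday
routines. Smartphone keystroke timestamps are a cheap, passive,
content-free window on those rhythms: every press event is a time-stamped
sample of when a person is awake and engaged with their phone. This
package implements an analysis that asks whether the *diurnal shape* of
typing activity, and its weekday/weekend stability, differs across
loneliness severity groups defined by the ULS-8 questionnaire.

## The measurement model

A participant's raw data is a stream of (press, release) timestamp pairs
in local clock time. The analysis uses only the press times. The day is
tiled by five half-open clock-time bins — sleep [00:00, 06:00), morning
[06:00, 12:00), afternoon [12:00, 17:00), evening [17:00, 21:00), night
[21:00, 24:00) — and each study date yields a count vector
$c = (c_1, \dots, c_5)$ and, when the day is non-empty, a ratio vector
$r_j = c_j / \sum_k c_k$.

Three conventions matter and are fixed package-wide:

* **Press defines the event.** A keystroke belongs to the date and bin of
  its press timestamp; the release timestamp is carried through I/O but
  unused. Typing counts, not durations, are the object of study.
* **Naive local time.** All timestamps are clock time in one fixed study
  timezone, stored internally as DST-free instants. Diurnal binning is a
  statement about the local clock, so no timezone arithmetic is ever
  applied.
* **Half-open intervals everywhere** (bins and study weeks), so
  boundaries are never double-counted.

## Completeness filtering

Field deployments lose days — participants switch keyboards back,
devices die. The study design discards the first week (adjustment to the
new keyboard) and then requires *complete weekly data in at least 3 of
the 4 remaining weeks*. "Complete" is operationalized as: all 7 days of
the week have a nonzero keystroke total. This is the strictest reading
available in a data model where a silent logger and an unused phone are
indistinguishable; it is exercised exhaustively (all $2^4$ week
patterns) in the test suite. Only days inside complete weeks enter a
participant's profiles, so a partially missing week never biases a mean.

## Averaging order for ratio profiles

A participant's mean ratio profile is the **average of per-day ratio
vectors** over retained non-empty days, not the ratio of summed counts.
The per-day form weights every day equally regardless of volume, which
matches a design where the quantity of interest is the typical *shape*
of a day. Days with zero total are skipped in the ratio average (0/0)
but still contribute to the mean-count profile. The pooled alternative
(summed counts over summed total) is available via
`ratio_method = "pooled"` on `participant_profile()` and
`analyze_daily_counts()`; the two differ whenever daily totals vary, and
no claim is made about which an individual prior study used.

## Shape statistic: the quadratic coefficient

Each participant's five-bin mean count profile is fitted by OLS with a
second-order polynomial $y = a_2 x^2 + a_1 x + a_0$. An evening-peaked
day (rise through the afternoon, fall at night) is concave, $a_2 < 0$; a
late-night/early-morning pattern is convex, $a_2 > 0$. The per-group
mean of per-participant fitted curves, and the correlation $r$ between
group-mean observed and fitted profiles, summarize fit quality.

The abscissa is deliberately the **bin index** $x = 1..5$, even though
the bins span unequal numbers of hours (6/6/5/4/3). Fitting a
five-element vector against its indices is the standard polyfit idiom
for this feature, and the coefficient is used only as a relative shape
score, never as a rate of change per hour. `abscissa =
"midpoint_hours"` switches to bin-midpoint clock hours (3, 9, 14.5, 19,
22.5) for sensitivity analyses. A constant profile fits exactly with
$a_2 = a_1 = 0$ but its observed/fitted correlation is reported as
undefined (`NA`), never 0.

## Weekday/weekend similarity

Routine stability is measured per participant as the cosine similarity
between the weekday and weekend mean ratio profiles. Cosine is scale
invariant — two days with the same shape but different volumes score 1 —
which is exactly the right invariance for ratio profiles, and for
nonnegative vectors it lies in [0, 1]. A participant with no non-empty
weekend (or weekday) day in their retained weeks has no defined
similarity; they are flagged and excluded from the group test with a
logged reason rather than imputed. Groups are compared on per-participant
similarities with Welch's t-test for every group pair; the very-severe vs
no-loneliness pair is the headline comparison. Pairs are oriented
lonelier-group-first, so a positive t means the lonelier group keeps the
more stable weekday/weekend routine.

## The statistical battery

Group tests are the classical ones: one-way fixed-effects ANOVA
($F = MS_{between}/MS_{within}$), Tukey–Kramer studentized-range
post-hoc pairs (the harmonic form, since the group sizes 18/26/10/5 are
unbalanced), and two-sided Welch's t with Welch–Satterthwaite degrees of
freedom. The implementations delegate to R's `stats` fitters behind a
uniform result interface; the test suite cross-checks all three against
independently coded textbook formulas to $10^{-6}$ on 100 seeded
datasets at the study's group sizes. $\alpha = 0.05$ throughout, with no
correction across the five time-section ANOVAs or the six similarity
pairs — the design runs exactly the stated battery and flags each test
at its own level. Degenerate inputs (zero within-group variance) are
reported as explicit degenerate results or errors, never silently
patched.

## The synthetic cohort generator

The generator exists so that the full pipeline — file ingestion through
group statistics — runs and is testable with no real data. It emulates:

* **Diurnal intensity**: per bin and day type, keystroke counts are
  Poisson with rate $\lambda_{g,b,d} \cdot m_i$, where $g$ is the group,
  $b$ the bin, $d \in \{\text{weekday}, \text{weekend}\}$, and $m_i$ a
  per-participant multiplier. Piecewise-constant intensity is used
  because the analysis only ever observes bin totals; finer temporal
  structure would be unidentifiable. Within a bin, press times are
  uniform at millisecond resolution.
* **Between-person volume spread**: $m_i$ is lognormal with mean 1 and
  log-scale sd 0.55, chosen to match a keystroke-volume coefficient of
  variation of about 0.6 over a four-week window (mean ≈ 127k, sd ≈ 76k
  keystrokes). The multiplier scales counts but cancels in ratios, so it
  spreads volumes without touching diurnal shape.
* **Day dropout**: each day is lost wholesale with probability 0.023,
  solved from the completeness rule — with week-completeness probability
  $q = (1-p)^7$ and inclusion probability $4q^3 - 3q^4$, $p = 0.023$
  yields ≈ 89% inclusion, i.e. the ~10% attrition a five-week deployment
  of this kind experiences.
* **Group-conditional shape**: defaults give the no/moderate/severe
  groups an evening-peaked weekday profile (150/700/1100/1600/950
  keystrokes per bin) that shifts toward the night on weekends
  (250/400/1000/1300/1550), and the very-severe group a night+sleep-
  peaked profile (1200/300/800/900/1300) identical across day types.
  Daily totals are ≈ 4,500 (≈ 127k/28). The shapes encode the three
  qualitative study findings — elevated sleep-time typing, convex
  profiles, and weekday/weekend stability in the very-severe group —
  whose published magnitudes are only available graphically; the
  defaults were chosen once for direction, not to replicate bar heights.
* **Banded questionnaires**: ULS-8 items are rejection-sampled uniform
  vectors conditioned on the group's total-score band. The analysis uses
  only the banded total, so no latent-trait structure is modelled.

Ground truth (multiplier, dropped days, every Poisson draw) is recorded,
and a test asserts that binning the generated event stream reproduces
the recorded draws integer-for-integer. Reproducibility uses a Lehmer-
style hash of the master seed and participant index, with separate
streams for questionnaire and events so the two stay aligned between the
event-level and counts-only generation paths.

### What the generator does *not* emulate

Sessions and bursts (real typing is clustered, not Poisson-uniform
within bins), autocorrelation across days, key identity and typing
speed, gradual (rather than day-level) missingness, and within-group
heterogeneity of diurnal shape. Consequently the synthetic effect sizes
are much cleaner than real ones — simulated F and t statistics on the
default profiles are an order of magnitude larger than anything a real
cohort would produce. Passing the direction-recovery experiments shows
the pipeline *detects what the generator encodes*; it is not evidence
about real-world effect sizes or power.

## Replicated experiments and problem sizes

Two experiment harnesses ship with the package (`run_simulation_study()`
and `analysis/03_replication_study.R`):

* **Null calibration**: all four groups drawn from one shared profile at
  sizes 18/26/10/5 with dropout disabled (so sizes stay exact); across
  2,000 replicates the sleep-bin ANOVA should reject at 5% ± 1.5%. The
  skewed lognormal volume multiplier makes this a mildly non-normal
  setting, so this doubles as a robustness check of the F-test at the
  study's unbalanced sizes. The acceptance suite runs the full 2,000;
  the analysis driver defaults to 500 for interactive use.
* **Direction recovery**: under the default paper-like profiles, 100
  replicates of the full pipeline; ≥ 90 must recover all three headline
  directions with significance. Replicates use the counts-only
  generation path, which is draw-for-draw identical to the event path.

Both experiments run the complete analysis per replicate (59
participants, 28 analysis days), a deliberate end-to-end choice over
testing stages in isolation.

## Degenerate inputs and edge policies

* Malformed event rows (unparseable timestamps, release before press)
  are skipped and counted, never repaired; a file with zero parseable
  rows is an error naming the path.
* Events outside the study window are dropped with a count.
* Duplicate identical events are retained: deduplication would silently
  alter counts and nothing in the data model distinguishes a true
  double-press from a logging artifact.
* Equal press timestamps keep file order (stable sort); no claim is made
  about the capture order of simultaneous touches.
* A group with fewer than 2 included participants is dropped from each
  affected test with an explicit note in the report, and the remaining
  eligible groups are still compared.
* Missing questionnaire items are a hard validation error; the analysis
  is defined for complete ULS-8 responses only.

## Known limitations

The pipeline analyzes *when* typing happens, not what or how fast; it
assumes a single-site cohort in one timezone; the completeness rule
cannot distinguish disuse from logging failure; and all calibration
evidence comes from the synthetic generator described above, with the
caveats listed there.
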