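---
title: "Deriving and comparing sleep measures from wrist actigraphy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving and comparing sleep measures from wrist actigraphy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(actisleep)
library(dplyr)
```

## The problem

Wrist-worn accelerometers summarize movement into per-epoch *activity
counts* (here, one-minute epochs). Turning a week of counts into sleep
measures is a three-stage pipeline:

1. **Sleep/wake scoring** — classify every epoch as sleep or wake from the
   counts (`score_cole_kripke()`);
2. **Sleep-period detection** — group the scored epochs into contiguous
   in-bed sleep sessions (`detect_sleep_periods()`, the Tudor-Locke
   algorithm);
3. **Sleep measures** — compute duration, efficiency, fragmentation and
   related measures per period (`compute_measures()`), aggregated per
   calendar day (`aggregate_daily()`).

The Tudor-Locke detector was validated on children with waist-worn devices.
In populations with restless sleep — chronic pain being the motivating
example — its default parameters split genuinely continuous nights at long
mid-sleep wake bouts, or miss nights entirely. This package therefore also
provides the machinery to *re-tune* the detector against self-report sleep
logs: a per-minute agreement statistic (`minute_agreement()`), an exhaustive
parameter grid search (`grid_search()`), and a method-comparison layer
(repeated-measures Bland–Altman limits of agreement and exact Wilcoxon
signed-rank tests) to quantify what the re-tuning changes.

## Stage 1: sleep/wake scoring

The minute-epoch Cole-Kripke rule scores epoch $t$ as

$$D(t) = 0.001\,(106\,A_{t-4} + 54\,A_{t-3} + 58\,A_{t-2} + 76\,A_{t-1}
      + 230\,A_{t} + 74\,A_{t+1} + 67\,A_{t+2}),$$

with sleep declared when $D(t) < 1$. Counts beyond the series boundaries
are treated as zero. All coefficients, the scale, the threshold and an
optional per-epoch count cap are exposed through `ck_config()` so published
variants can be swapped in; the default applies no cap and uses counts
exactly as provided by the file's producer — whether those are single-axis
or vector-magnitude counts is a property of the upstream device export, not
of this package. No rescoring rules are applied after classification.

Because all weights are non-negative, raising any count can only move
epochs from sleep to wake, never the reverse; the tests exercise this
monotonicity alongside an epoch-by-epoch reference implementation.

## Stage 2: Tudor-Locke sleep-period detection

Five parameters (`tl_params()`) govern a single left-to-right scan:

| parameter | default | meaning |
|---|---|---|
| `bedtime_def` | 5 | consecutive sleep epochs that open a period |
| `waketime_def` | 10 | consecutive wake epochs that terminate it |
| `min_period_len` | 160 | minimum accepted duration (min) |
| `min_nonzero_epochs` | 0 | minimum epochs with count ≥ 1 |
| `max_period_len` | 1440 | periods must be < 24 h |

Three behaviours were genuinely open and are fixed here as follows:

* **Trailing wake is trimmed.** The terminating wake run marks the end of a
  period but does not belong to it: the period closes at the last sleep
  epoch before the run. This keeps the construction symmetric (periods
  start *and* end on sleep epochs) and stops out-of-bed wake from diluting
  efficiency. A direct consequence is that sleep-onset **latency is
  structurally zero** for every detected period — the first epoch is sleep
  by construction — so latency is only informative for log-defined periods.
* **Rejected candidates do not block later periods.** When a candidate
  fails the length or non-zero filters, scanning resumes immediately after
  the terminating wake run, exactly as it would had the candidate been
  accepted. This makes candidate boundaries independent of the filters —
  a property the grid search exploits (below).
* **A series ending mid-period** closes the period at its last sleep epoch
  and filters it normally; a candidate longer than `max_period_len` is
  discarded, not truncated.

Log-defined periods (`periods_from_log()`) cover the half-open interval
`[in_bed, out_bed)` on the epoch grid and are exempt from all filters. Log
timestamps are rounded to the nearest whole minute with ties rounding down,
a convention needed because diaries rarely state a resolution.

## Stage 3: sleep measures

Ten measures per period: latency, efficiency (`100·TST/TIB`), total
minutes in bed (TIB), total sleep time (TST), wake after sleep onset
(WASO), number of awakenings, average awakening length, movement index
(percent of epochs with count ≥ 1), fragmentation index, and their sum, the
sleep fragmentation index. `TIB = latency + TST + WASO` holds exactly for
every period and every day.

Two definitional ambiguities are resolved explicitly:

* **Fragmentation index.** Published descriptions disagree between a
  bout-ratio form (one-minute sleep bouts over all sleep bouts) and a
  TST-denominator form. The bout-ratio form is the default — it is the one
  consistent with daily pooling ("count of one-minute sleep epochs divided
  by count of sleep segments") — and the alternative is selectable with
  `fi_denominator = "tst"` for sensitivity checking.
* **Average awakening length on a perfect night** is reported as 0 rather
  than undefined, so complete-case and zero-imputation analyses treat
  awakening-free nights identically.

Daily aggregation (`aggregate_daily()`) sums the additive measures and
*pools* the ratios: daily efficiency is `100·ΣTST/ΣTIB`, not the mean of
per-period efficiencies (summing percentages across periods of different
lengths would be unit-inconsistent, which is also why the daily sleep
fragmentation index is the sum of the *pooled* movement and fragmentation
indices). A period belongs to the calendar day containing its final
epoch's start, so a period ending exactly at midnight still belongs to the
earlier day, and nights are assigned to the morning they end on.

## The agreement statistic and the grid search

For one participant, let $A$ be the set of minutes inside any detected
sleep period and $B$ the set inside any logged period. The percentage of
agreement is the Jaccard index $|A \cap B| / |A \cup B|$ over the whole
recording span. Within-period wake minutes count as asleep — diaries do not
record mid-night wake — and a night where detection fails entirely
contributes its full logged window to the denominator, which is precisely
the penalty that motivates this statistic over chance-corrected
coefficients: failing to find a night should hurt. Participants enter the
cohort summary as an unweighted mean (`cohort_agreement()`), so a
participant with more recorded nights does not dominate.

`grid_search()` evaluates the detector over a Cartesian grid
(`grid_spec()`; the default spans 6·6·7·6 = 1512 parameter sets with the
maximum length fixed at 1440). Because candidate periods depend only on
`bedtime_def` and `waketime_def`, the search enumerates candidates once per
(bedtime, waketime) pair per participant and applies the remaining two
parameters as per-candidate filters; the tests verify cell-for-cell
equality with running the detector directly. The search is deterministic;
ties in mean agreement are broken by enumeration order (`bedtime_def`, then
`waketime_def`, then `min_period_len`, then `min_nonzero_epochs`, each
ascending), and `summarize_parameter_effects()` reports marginal means per
parameter value. Agreement is computed over the full recording span rather
than per-night windows; the minute-set formulation makes per-night matching
unnecessary.

## Method comparison

Daily measures from several methods are joined on (participant, day)
(`paired_daily_table()`); a missing cell means that method detected no
period that day. `missed_night_report()` counts such nights against the
sleep log. Two missing-data strategies are provided
(`apply_missing_strategy()`): complete-case (drop unpaired days) and
zero-imputation, which coincide on fully observed tables.

**Limits of agreement.** With several days per subject and a true quantity
that varies day to day, the variance of a single between-method difference
is estimated by one-way random-effects ANOVA on subjects:
$\sigma_d^2 = \sigma_b^2 + \sigma_w^2$, where $\sigma_w^2$ is the residual
mean square and $\sigma_b^2 = (\mathrm{MSB} - \mathrm{MSW})/n_0$ (floored
at zero) with $n_0 = (N - \sum n_i^2/N)/(k-1)$ for unequal replicates. The
95% limits are $\bar d \pm 1.96\,\sigma_d$, with both components exposed
for audit. When every subject contributes exactly one day the partition is
unidentifiable and the classic single-level limits are reported with a
message.

**Wilcoxon signed-rank tests** compare per-participant mean measures
between method pairs. Zeros are dropped (the classical treatment, matching
the behaviour of standard software defaults rather than the Pratt
adjustment); with ≤ 25 untied non-zero differences the exact distribution
is used, otherwise the normal approximation with tie and continuity
corrections. A pair whose differences are identically zero by construction
— latency between two Tudor-Locke variants — is reported as degenerate
rather than tested. P-values are reported raw, without multiplicity
correction, mirroring how such panels are conventionally presented.

## The synthetic cohort generator

`generate_cohort()` simulates a cohort with known ground truth so every
stage runs and is tested without access to raw study data. Per night it
draws a true sleep window (bedtime and time-in-bed jittered around their
means), places Poisson-many awakening bouts of uniform length inside it
without overlap, and fills counts: waking epochs from a zero-inflated
negative binomial with a high mean, sleeping epochs zero except for
movement epochs (`Bernoulli(movement_prob)`) with small positive counts.
The sleep log is the true window plus independent Gaussian recall noise on
each boundary, truncated so windows stay positive. Generation is a pure
function of the specification and seed.

`chronic_pain_preset()` fixes the study conditions used throughout the
tests and the acceptance script: 16 participants, 7 nights, mean time in
bed 538 min with 30/45-min night-to-night jitter, 3 awakening bouts per
night of 12–20 min (the long pain-flare-like bouts that defeat a 10-minute
terminator), movement probability 0.12, recall noise SD 15 min, and no
non-wear (emulating participants who consistently wear the device in bed;
a non-wear option exists to exercise the non-zero-epochs filter and the
wear-fraction eligibility rule, whose threshold defaults to 0.8 of the
logged window). The count distributions are synthetic conveniences chosen
so the default scorer separates the states cleanly; the generator does not
emulate circadian drift, naps by default (an option exists), device-axis
differences, or the heavy-tailed movement bursts of real accelerometry —
so passing tests demonstrate correctness of the algorithms and the
direction of the optimization, not field accuracy of any parameter set.

```{r example}
cohort <- generate_cohort(chronic_pain_preset(), seed = 1)
res <- grid_search(cohort, grid_spec())
select(res, bedtime_def:min_nonzero_epochs, mean_agreement) |> head(3)

# default vs optimized agreement on this cohort
cell <- function(bt, wt, ml, mnz) {
  r <- filter(res, bedtime_def == bt, waketime_def == wt,
              min_period_len == ml, min_nonzero_epochs == mnz)
  r$mean_agreement
}
c(default = cell(5, 10, 160, 0), optimized = cell(5, 25, 160, 5))
```

On restless cohorts the selected `waketime_def` exceeds the 12–20-minute
bout length, and the optimized preset `tl_chronic_pain()` (5, 25, 160, 5,
1440) agrees with the sleep log substantially better than the defaults —
the direction the re-tuning exists to demonstrate.

## Numerical and scale choices

* All timestamps are handled in UTC on a strict one-minute grid; epoch
  `i` covers `[start + (i-1) min, start + i min)` and every boundary rule
  (log rounding, day assignment, log-period coverage) follows from that
  half-open convention.
* The pipeline and grid search are deterministic; the only randomness in
  the package is the generator's, controlled by an explicit seed.
* Test and acceptance problem sizes — cohorts of 2–16 participants with
  5–7 nights, 1000 randomized series of up to 10^4 epochs for the
  brute-force cross-checks, 20 seeds for the directional claims, a 50 × 5
  simulation for the variance-component recovery — were chosen as the
  smallest scales at which each property is meaningfully exercised.
* `run_pipeline()` writes all numeric output at full precision and
  reproduces outputs byte-for-byte on identical inputs; its manifest
  records a configuration hash and input checksums rather than timestamps
  for that reason.

## Limitations

The package consumes epoch counts; raw 30 Hz acceleration, proprietary
count conversion, device-specific sleep detectors and the 2018 revision of
the period-detection algorithm are out of scope. Re-tuned parameters
optimize agreement with self-report logs, which are themselves subject to
recall bias — agreement with a diary is not validity against
polysomnography.
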