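---
title: "Methods: diary-versus-wearable sleep agreement in nightfit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diary-versus-wearable sleep agreement in nightfit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nightfit)
```

## The measurement model

Each night of a cohort study yields up to two observations of the same
sleep episode: a device record (onset, offset, `minutesAwake`, a main-sleep
flag) and a morning diary entry collected through a button interface (bed
time, fall-asleep time, wake time, self-reported actual sleep time, a
4-level quality rating). `nightfit` treats the device as the reference
*instrument* — not the truth — and quantifies agreement between the two
methods in the Bland–Altman framework: for paired differences
$d_i = \text{device}_i - \text{diary}_i$ it reports
$\bar d$, $s_d$ (sample SD, $n-1$ denominator), limits of agreement
$\bar d \pm 1.96\,s_d$, and a two-sided paired $t$ test of $\bar d = 0$.
The sidedness and the $n-1$ denominator are this package's choices: the
source design reports paired-$t$ p-values without stating either, and the
observed p-value pattern is consistent with two-sided tests.

Two analysis weights coexist deliberately. Participant-level analyses
(overall and demographic strata) first average the nightly differences
within each participant, then analyze the per-participant means — every
sleeper counts once, however many nights they contributed. Nightly
quality-of-sleep strata instead pool nights across participants, because
the quality rating varies night by night.

## Clock arithmetic

All clock-valued quantities live as integer seconds since midnight in
$[0, 86399]$; durations are integer seconds. Printed `h:mm:ss` appears
only at report time, so minute- and second-resolution inputs mix without
float error.

Sleep straddles midnight, so plain means of clock seconds are wrong
(23:00 and 01:00 must average to 00:00, not noon). The package lifts
times onto a signed *anchored* axis: with the default noon anchor, times
in $[12{:}00, 24{:}00)$ map to negative seconds (the evening before) and
morning times to positive seconds, a bijection with range
$(-43200, 43200]$. Means, paired clock differences, and the ordering check
all operate on this axis. The anchor choice is the package's own: sleep
onsets in the target population cluster around midnight, and noon is
maximally far from that cluster. A time exactly on the anchor has no
defined night and raises an error rather than being silently assigned;
the synthetic generator therefore never emits the exact anchor instant
(it nudges such values one grid step).

Elapsed spans use modular arithmetic, `(end - start) mod 86400`, strictly
positive — a zero-length sleep is treated as an input error, never a valid
record.

## Quality control and matching

Records join on `(participant, sleep-end date)`. QC statuses, checked in
this order:

1. **AM/PM error** — the diary fall-asleep or wake time differs from the
   device counterpart by more than 9 h (configurable) *and* the absolute
   difference lies within 3 h of 12 h. The 12-hour check runs first
   because a 12-hour slip on one field usually also breaks the
   bed/asleep/wake order; without the precedence, almost every AM/PM slip
   would be mislabelled an ordering error.
2. **Order violation** — bed $\le$ asleep $<$ wake fails on the anchored
   axis. Bed may equal asleep (the button grid is coarse); a wake equal to
   asleep is a violation.
3. **Overlarge difference** — beyond 9 h but not AM/PM-like.

Excluded nights are tallied, never corrected: re-shifting an apparent
AM/PM slip by 12 h would fabricate data the participant did not enter.
The 9-hour rule is applied to the two clock fields the device also
measures (onset, offset), not to the reported sleep amount — the source
design names no field, and the clock fields are what it compares.

Participant selection keeps the chronologically *first* 14 calendar days
of device data, then includes a participant iff at least 7 of those nights
are QC-valid matched nights. Response-latency compliance buckets are
half-open, $[0,3), [3,6), \dots, [15,\infty)$ hours, making the buckets a
partition (the printed labels of the source tables do not fix the
boundary).

## Derived variables

Per night: diary TST = wake − asleep (wrap-aware); diary AST = the
reported amount; device TST = end − start; device WASO =
`minutesAwake` × 60, stored bit-faithfully in minutes and converted only
here; device AST = TST − WASO, exactly. Differences are device − diary,
so a positive clock difference means the device time is later, and a
positive duration difference means the device value is longer. On any
night set where both sources' offsets fall on the same side of the anchor,
the TST difference decomposes exactly as
$d_{\text{TST}} = d_{\text{offset}} - d_{\text{onset}}$; the test suite
asserts this linearity.

## Descriptive statistics

**Heaping profile.** Minute-of-hour values are counted on the 12-bin
5-minute grid; `grid_fraction` is the share on $\{0, 30\}$. Survey
fall-asleep times are first derived as bed time + latency; device times
(1-second resolution) are snapped to the nearest 5-minute bin, ties —
exactly 2.5 min — rounded down. If each 5-minute bin were equally likely,
`grid_fraction` would be $2/12$; self-reports exceed this massively, and
the generator's heaping parameter reproduces that.

**Coverage.** The fraction of nights whose difference lies within ±30
(±60) min, optionally after subtracting the full-sample mean difference
(`global_mean`) or the good/poor-night stratum means (`by_qos`,
nights-first — consistent with how the night counts are published).
Correction means are in-sample, not leave-one-out. The boundary is
*inclusive* by default (`|d| ≤ 30` min) with a strictness flag: the
source text mixes "less than 30 minutes" and "within ±30", and diary
values sit on the half-hour grid, so the boundary carries real mass —
the choice is therefore exposed, not hidden. Corrections never drop a
night, and coverage is monotone in the threshold; both are asserted as
properties.

## The synthetic cohort generator

The generator emulates the *statistical structure* of the study's data,
not sleep physiology:

* Device onset clusters near 00:20 with a ~70-min marginal SD; device TST
  near 7:08 (SD ~53 min); WASO 58 (SD 24) min truncated to
  $[0, \text{TST} - 30\,\text{min}]$. Marginal SDs are split into
  between-participant and within-night components (55/43 and 40/35 min);
  the split itself is unreported anywhere and was chosen once on the
  judgment that stable per-person tendencies dominate self-report error.
* Diary times are truth plus a per-participant report intercept
  (onset +8.65 min late, offset −5.65 min early, SD 25 min) plus nightly
  noise (SD 15 min), then snapped to the 5-minute button grid, then
  heaped to the nearest :00/:30 with probability `heap_prob_30 = 0.49`
  (calibrated so the marginal on-grid share
  $h + (1-h)/6 \approx 57.6\%$). Heaping ties — exactly 15 min from both
  half-hours — break toward the full hour, the simplest mechanism
  consistent with the published marginal rates.
* Reported AST is device TST − WASO plus a quality-conditional bias
  (+19.2 min on good-rated nights, −2.5 on poor), a per-participant
  intercept (SD 30 min) and nightly noise (SD 35 min).
* A latent per-participant quality trait (loading `qos_corr = 0.6`)
  couples the survey group (good/poor sleeper) and the nightly ratings;
  the coupling strength has no published value and is configurable. The
  marginal rates (70% good nights, 60% good-group) are matched exactly by
  construction.
* AM/PM slips (±12 h on one field), ordering errors (asleep pulled 30 min
  before bed) and per-night missingness are injected at configurable
  rates, each injection recorded in a ground-truth ledger alongside the
  latent truth for every night — parameter-recovery and QC-recovery tests
  run against this ledger.
* Determinism: every participant draws from an RNG sub-stream derived by
  stable string hashing from the cohort seed, so enlarging the cohort
  leaves existing participants' records byte-identical.

Two deliberate fix-ups keep the stated world self-consistent: independent
heaping of bed and fall-asleep times can cross them by up to 30 min, and
the generator clamps bed back to fall-asleep (a real diary UI would not
let bed follow asleep); and the exact noon instant is never emitted (see
above). Both affect well under 1% of nights.

What the generator does **not** emulate: sleep stages and naps, circadian
drift across the fortnight, weekday/weekend structure, device algorithm
changes, or heaping that depends on the distance to the half-hour. A green
recovery test therefore establishes that the pipeline correctly measures
the biases of *this* world — it cannot certify the device, nor the
published cohort's unpublished raw data.

## Numerical conventions

* Circular means round to the nearest whole second (R's `round`);
  anchored mapping and modular spans are exact integer arithmetic.
* Printed percentages and minute values round half *away from zero* to
  one decimal (`543/736 → 73.8`), matching the published tables; base R's
  banker's rounding would disagree on ties.
* Zero-variance difference sets return limits equal to the mean and an
  undefined (`NA`) p-value rather than erroring.
* Strata with fewer than 2 observations report `NA` statistics, not
  errors; empty inputs to means, histograms and coverage are errors.

## Known limitations

* The AM/PM classification window (12 ± 3 h) is a heuristic; a slip
  combined with a very large genuine reporting error can still be binned
  as an overlarge difference. Both statuses are excluded either way.
* The published offset mean difference (5:38) is not exactly recoverable
  from the printed per-source means (they round to 1 s and differ by
  5:39); the acceptance surface recomputes the three differences that are
  exactly recoverable and checks limits of agreement to table rounding
  (0.1 min).
* Repeated-measures Bland–Altman variance corrections and regression-based
  limits are out of scope; the simple LoA formula is used throughout, as
  in the source design.
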