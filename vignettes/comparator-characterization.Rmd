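---
title: "Characterizing comparator data for CGM performance studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing comparator data for CGM performance studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dgrtools)
```

## The problem

The clinical performance of a continuous glucose monitoring (CGM) system is
judged by comparing sensor readings against comparator (reference) blood
glucose (BG) measurements. What the comparison shows depends heavily on
*which* glycemic situations the comparator data cover: accuracy tends to
degrade during hypoglycemia and during fast glucose changes, so a study
that under-samples those situations reports flattering numbers. `dgrtools`
implements a characterization framework for comparator data that makes
this coverage explicit and checkable: it pairs each comparator value with
its rate of change (RoC), classifies the pairs into five clinically
motivated regions of the (BG, RoC) plane — the dynamic glucose region
(DGR) plot — and tests the resulting distribution against recommended
minimum percentages.

## RoC-BG pairing

During an in-clinic frequent sampling period (FSP), comparator
measurements are taken every 15 minutes, typically over 7 hours (29
samples). Each BG value after the first is paired with the RoC computed
from it and its predecessor,

\[ \mathrm{RoC}_i = \frac{BG_i - BG_{i-1}}{t_i - t_{i-1}}, \]

so a 29-sample session yields 28 RoC-BG pairs and there is no pair for
time zero. The RoC always uses the *actual* interval, because session
schedules drift; pairs whose interval deviates from the nominal grid by
more than a tolerance (default 5 minutes) are kept but flagged, and
flagged pairs are excluded from compliance checking and elimination by
default. Pairs never span sessions or subjects. The mean absolute RoC
(MARoC) summarizes how dynamic a pair set is.

## The five DGR regions

With all constants in mg/dL and mg/(dL·min):

| Region | Definition |
|---|---|
| BG low | BG < 70, any RoC |
| BG high | BG > 300, any RoC |
| Alert low | BG ≥ 70, RoC < −1, and BG + 30·RoC < 70 |
| Alert high | BG ≤ 300, RoC > +1.5, and BG + 30·RoC > 250 |
| Neutral | everything else |

The projection `BG + 30·RoC` is the linear 30-minute extrapolation at the
current RoC; it tilts the inner border of the alert regions (the Alert-low
border is tilted below BG = 100 and flat at RoC = −1 above; the Alert-high
border is tilted below BG = 205 and flat at RoC = +1.5 above). A
deliberate convention, stated prominently because boundary data are
common: every boundary case (BG exactly 70 or 300, RoC exactly −1 or
+1.5, projection exactly hitting 70 or 250) falls to *Neutral*, because
the critical-region inequalities are strict where written strict. The
only non-strict edges are BG ≥ 70 (Alert low) and BG ≤ 300 (Alert high).

```{r}
classifyRoCBG(bg = c(60, 310, 90, 200, 150), roc = c(2, -2, -1.5, 2, -1.5))
```

## The recommended distribution and compliance

The recommendation is that at least 7.5% of pairs lie in *each* of the
four critical regions, which automatically leaves at most 70% in the
neutral region (4 × 7.5% + 70% = 100%). Compliance is decided with exact
integer arithmetic (`count · 10000 ≥ 750 · n`), never with floating-point
fractions, so that a region holding exactly 7.5% (e.g. 3 of 40 pairs)
passes the inclusive bound. Displayed percentages are rounded to one
decimal, half away from zero; the exact rationals are what decide.

## Neutral-region elimination

When a study misses the recommendation, the least critical neutral pairs
can be discarded deterministically. Each pair's elliptical distance from
the neutral-region center is

\[ D = \sqrt{\left(\frac{\mathrm{RoC}}{a}\right)^2 +
             \left(\frac{BG - BG_c}{b}\right)^2}, \]

with a = 1 mg/(dL·min), b = 115 mg/dL, BG\(_c\) = 185 mg/dL. The locus
D = 1 passes through (RoC 0, BG 70), (RoC 0, BG 300) and (RoC ±1,
BG 185): the ellipse spans exactly the horizontal edges of the neutral
region. Neutral pairs are excluded one at a time in ascending order of D,
re-evaluating compliance after each, until every critical region meets
its minimum.

Properties worth knowing:

* Only neutral pairs are candidates, so removals never touch a critical
  region and only shrink the denominator. Consequently the greedy count
  equals the true minimum, which has the closed form
  `k = max(0, n − floor(c_min·10000/750))` for the scarcest critical
  count `c_min` (`minExclusions()`), and the test suite verifies greedy =
  exhaustive minimum over a thousand random instances.
* Ties at equal D are broken by (session, time, input order), so results
  are bit-reproducible without random sampling.
* If any excluded pair has D > 1, the ellipse would reach into the BG
  low/high bands; the run completes but is flagged `adequate = FALSE`
  with a warning — a soft flag, not a failure, since the underlying data
  may merely be borderline. If a critical region holds zero pairs, no
  elimination can help (0/(n−k) never reaches 7.5%) and the run returns
  `feasible = FALSE` without excluding anything.

## Episode analysis of CGM traces

For validating the alert regions against real sensor behaviour, the
package detects glycemic episodes in CGM traces: maximal runs of
consecutive readings strictly below 70 mg/dL (hypoglycemia) or strictly
above 250 mg/dL (hyperglycemia), with runs broken at sampling gaps.
Episode duration is counted as the time *spanned* between the first and
last beyond-threshold sample, `(run length − 1)·Δ`; the alternative
`run length·Δ` convention is available via
`EpisodeConfig(durationConvention = "count")` since consensus definitions
are ambiguous on this point. With 5-minute sampling, the default means an
episode needs at least 4 sub-threshold samples to reach the 15-minute
minimum; episodes longer than 120 minutes are reported but excluded from
the analysis set.

An episode *qualifies* when the full 60 minutes before it are observed
without gaps, stay on the in-range side of the threshold, and change
monotonically toward it (RoC ≤ 0 before hypoglycemia, RoC ≥ 0 before
hyperglycemia, both non-strict so flat stretches are allowed).
Qualified episodes are summarized AGP-style: traces aligned at episode
start, per-offset percentiles (5/25/50/75/95). Percentiles use linear
interpolation between order statistics of type 6, which clamps the
extreme bands to the extreme order statistics at small n (two traces at
100 and 200 mg/dL give 5th/95th bands of exactly 100 and 200, not
interpolated beyond the data). `projectSummaryToDGR()` turns a percentile
curve back into (BG, RoC) coordinates by difference quotients, optionally
smoothed with a centered moving average (default window 3 points; the
smoothing method is a choice — only "interpolated and smoothed" is
prescribed).

## The synthetic-data generator

The generator emulates the proposed testing procedures and is the
package's test bed; it is shape-based, not a physiological
insulin–carbohydrate model, because the procedures specify glycemic
*targets*, not mechanisms.

**In-clinic sessions** follow the target glucose profile: start stable in
range, post-meal rise (insulin bolus withheld), ~30 min sustained above
300 mg/dL, rapid fall, ~30 min maintained below 70 mg/dL, recovery to
100–180 mg/dL; 7-hour FSP on the 15-minute grid. It is built from anchor
points with monotone (`monoH.FC`) interpolation, per-session jitter on
anchor times (sd 20 min, reflecting the visible spread in hypoglycemia
timing between sessions) and levels (sd 15 mg/dL), and multiplicative
comparator noise (CV 2%, laboratory-grade). Plateau durations get only
mild jitter (sd 5 min) so the "sustained ~30 min" episodes survive. The
anchor layout was designed so that the profile places roughly 11% of its
28 pairs in each critical region (~57% neutral) — the stated design
target of the profile; the fall is concave (steep, then easing to about
−1.8 mg/(dL·min)) because a constant-slope descent spends exactly 30
minutes inside the Alert-low region (the tilted border *is* the 30-minute
projection) and therefore contributes only ~2 pairs, while a concave
descent enters the region earlier. A fraction of sessions (default 22%,
i.e. `manipulationFraction = 0.78`) instead follows a routine-therapy
shape: moderate post-meal excursion to 200–250 mg/dL, no induced
hypoglycemia, a late second meal. All generated values are clamped to
[40, 400] mg/dL.

**Free-living days** draw the seven-point capillary profile (before and
2 h after each main meal, and at bedtime) with timing jitter, duplicate
measurements around a latent value, and a third measurement exactly when
the duplicate retest rule fires (relative difference to the first
measurement exceeding ±10% at ≥100 mg/dL, or ±10 mg/dL below). The
capillary meter CV defaults to 5%, a typical value for a meter meeting
current accuracy standards (the framework itself does not fix this
number). Duplicates resolve to their mean; triples to the median, a
robust choice the framework leaves open, taken here so a single handling
error cannot dominate.

**Scheduling** assigns each participant one in-clinic day from each of
{1,2,3}, {7,8,9}, {13,14,15} for the 14-day sensor design, balanced so
that across the cohort the nine candidate days differ in usage by at most
one; at least 75% of participants are assigned type 1 diabetes.

What the generator does *not* emulate: sensor error (MARD-style accuracy
evaluation is out of scope), meal/insulin pharmacokinetics, circadian
structure in the free-living latent values, and real between-subject
heterogeneity beyond anchor jitter. Tests passing on synthetic cohorts
therefore demonstrate that the *mechanisms* (pairing, classification,
compliance, elimination, episode rules) behave as specified, not that any
particular real study will be compliant.

## Numerical choices and degenerate inputs

* Unit conversion uses 1 mmol/L = 18.016 mg/dL exactly; internal values
  are never rounded; display rounding is 1 decimal for mmol/L, 2 decimals
  for RoC in mmol/(L·min), half away from zero.
* Ingested glucose outside [10, 600] mg/dL is rejected as implausible;
  classification itself applies no reportable-range clamp, since
  comparator values are laboratory measurements.
* Series need ≥ 2 samples for pairing; empty pair sets, empty episode
  sets and all-flagged inputs raise errors rather than returning empty
  summaries silently.
* Compliance never relies on floating point (integer cross
  multiplication at a resolution of 1e-4 on requirement fractions).
* Aligned-summary offsets observed in fewer than `minTraces` traces are
  masked as `NA` rather than summarized.

## Problem sizes used in the test suite

The packaged checks run on desk-scale data chosen to exercise every code
path: single sessions of 29 samples, pooled sets of 50 sessions,
100-replicate compliance studies of the generator, 1000 random
elimination instances with n ≤ 60, descent cohorts of 400 traces, and a
500 × 500 classification grid. Real studies (hundreds of sessions,
thousands of pairs) are well within the same code paths; the
implementation is vectorized over pairs.

## Known limitations

* The "steeper descents" subset highlighted in real-world episode
  analyses is not implemented as a selector, because no defining
  threshold is specified; callers can filter aligned summaries by
  percentile instead.
* Session scheduling is implemented for the canonical 14-day,
  three-session design; other lifetimes error rather than guessing a
  tercile layout.
* The elimination procedure is the deterministic elliptical-distance
  rule only; random subsampling or stratified thinning are deliberately
  out of scope.
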