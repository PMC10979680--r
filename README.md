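# dgrtools

Characterization of comparator (reference) blood glucose data for the
clinical performance evaluation of continuous glucose monitoring (CGM)
systems.

When a CGM system is evaluated, sensor readings are compared against
comparator BG measurements collected during in-clinic frequent sampling
periods and free-living days. The observed accuracy depends strongly on
which glycemic situations the comparator data cover — hypoglycemia,
hyperglycemia and fast glucose changes are exactly where accuracy tends
to degrade, and exactly what ad-hoc study designs under-sample. This
package implements a characterization framework that makes the coverage
explicit and checkable:

- **RoC-BG pairing** — each comparator value `BG_i` is paired with the
  rate of change `RoC_i = (BG_i − BG_{i−1}) / (t_i − t_{i−1})` from its
  predecessor (no pair for time zero; a 7-h session on the 15-min grid
  gives 28 pairs), summarized by the mean absolute RoC (MARoC).
- **Dynamic glucose region (DGR) classification** — five regions of the
  (BG, RoC) plane: *BG low* (BG < 70 mg/dL), *BG high* (BG > 300),
  *Alert low* (BG ≥ 70, RoC < −1 mg/(dL·min), BG + 30·RoC < 70),
  *Alert high* (BG ≤ 300, RoC > +1.5, BG + 30·RoC > 250), and *Neutral*.
- **Distribution compliance** — at least 7.5% of pairs in each critical
  region (hence at most 70% neutral), decided in exact integer
  arithmetic.
- **Neutral-region elimination** — when a study falls short, the least
  critical neutral pairs are discarded deterministically in ascending
  order of the elliptical distance
  `D = sqrt((RoC/a)² + ((BG − BG_c)/b)²)` (a = 1 mg/(dL·min),
  b = 115 mg/dL, BG_c = 185 mg/dL) until every critical region meets its
  minimum; excluding any pair with D > 1 flags the data set as possibly
  inadequate.
- **Episode analysis** — detection and qualification of hypo-/hyperglycemic
  episodes in CGM traces (≥ 15 min and ≤ 120 min beyond threshold, 60-min
  gap-free monotone in-range lookback) with AGP-style aligned percentile
  summaries and projection back onto the DGR plane.
- **Synthetic data** — a generator for target-glucose-profile in-clinic
  sessions, routine-therapy sessions, free-living seven-point duplicate
  capillary days (with the ±10% / ±10 mg/dL retest rule), and balanced
  session scheduling across a 14-day sensor lifetime.
- **Reporting** — DGR plots with region backgrounds and side panels, and
  versioned JSON study reports. A thin command-line front end lives at
  `inst/scripts/dgr.R` (subcommands `classify`, `report`, `eliminate`,
  `episodes`, `simulate`, `plot`).

## Worked example

```r
library(dgrtools)

# simulate eight in-clinic sessions following the target glucose profile
sessions <- lapply(1:8, function(i)
  generateSession(SessionParams(manipulationFraction = 1), seed = i,
                  subjectId = sprintf("P%02d", i)))

pairs <- computePairs(sessions)
report <- distributionReport(pairs)
report
#> DistributionReport: n = 224, COMPLIANT
#>   BG_LOW        26  ( 11.6%)
#>   BG_HIGH       18  (  8.0%)
#>   ALERT_LOW     25  ( 11.2%)
#>   ALERT_HIGH    25  ( 11.2%)
#>   NEUTRAL      130  ( 58.0%)

maroc(pairs)
#> [1] 1.310309
```

Every session contributes 28 RoC-BG pairs; here all four critical regions
exceed the 7.5% minimum, so the pooled distribution is compliant and no
elimination is needed. `distanceD(bg = 70, roc = 0)` returns exactly `1`
— the elimination ellipse at D = 1 touches the horizontal edges of the
neutral region. For a non-compliant set, `eliminatePairs(pairs)` returns
the minimal exclusion set:

```r
res <- eliminatePairs(somePairs)
res@k                   # number of excluded neutral pairs
formatPercent(res@k / res@before@nTotal)  # e.g. 3.1 (% of all pairs)
isCompliant(res@after)  # TRUE when feasible
```

Plots: `renderDGRPlot(pairs)` draws the DGR plane with colored regions,
the pairs, and a side panel with per-region percentages, n and MARoC;
`saveDGRPlot()` writes PNG/PDF/SVG.

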