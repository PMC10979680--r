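## DGR region classification and distribution compliance.

#' Classify RoC-BG pairs into DGR regions
#'
#' @description `classifyRoCBG()` assigns each (bg, roc) point to one of
#' the five DGR regions. Predicates are evaluated in the order forced by
#' the region definitions:
#' \enumerate{
#'   \item `BG_LOW` if `bg < bgLow` (any RoC);
#'   \item `BG_HIGH` if `bg > bgHigh` (any RoC);
#'   \item `ALERT_LOW` if `bg >= bgLow`, `roc < alertLowRoC` and the
#'     30-minute projection `bg + horizon * roc < hypoTarget`;
#'   \item `ALERT_HIGH` if `bg <= bgHigh`, `roc > alertHighRoC` and
#'     `bg + horizon * roc > hyperTarget`;
#'   \item `NEUTRAL` otherwise.
#' }
#' All inequalities are strict or non-strict exactly as written above, so
#' boundary points (bg exactly 70 or 300 mg/dL, roc exactly -1 or
#' +1.5 mg/(dL*min), projection exactly hitting the target) fall to
#' `NEUTRAL`. Boundary data are common; this convention is deliberate and
#' symmetric in both alert regions.
#'
#' The projection is the linear extrapolation at the current RoC; the
#' upper border of `ALERT_LOW` is therefore tilted for bg below 100 mg/dL
#' (where `(70 - bg)/30 > -1`) and flat at roc = -1 above, and the lower
#' border of `ALERT_HIGH` is tilted below bg = 205 mg/dL and flat at
#' roc = +1.5 above.
#'
#' @param bg numeric vector, glucose in mg/dL (no reportable-range
#'   clamping: comparator values are laboratory measurements).
#' @param roc numeric vector, rate of change in mg/(dL*min).
#' @param cfg a [RegionConfig-class].
#' @return `classifyRoCBG()`: a factor with levels `dgrRegions()`.
#' @examples
#' classifyRoCBG(c(60, 310, 90, 200), c(2, -2, -1.5, 2))
#' @export
classifyRoCBG <- function(bg, roc, cfg = RegionConfig()) {
  if (!is.numeric(bg) || !is.numeric(roc) || length(bg) != length(roc)) {
    stop("bg and roc must be numeric vectors of equal length")
  }
  if (any(!is.finite(bg)) || any(!is.finite(roc))) {
    stop("bg and roc must be finite")
  }
  if (any(bg <= 0)) stop("bg must be positive")
  proj <- bg + cfg@horizon * roc
  lab <- rep("NEUTRAL", length(bg))
  alertHigh <- bg <= cfg@bgHigh & roc > cfg@alertHighRoC & proj > cfg@hyperTarget
  lab[alertHigh] <- "ALERT_HIGH"
  alertLow <- bg >= cfg@bgLow & roc < cfg@alertLowRoC & proj < cfg@hypoTarget
  lab[alertLow] <- "ALERT_LOW"
  lab[bg > cfg@bgHigh] <- "BG_HIGH"
  lab[bg < cfg@bgLow] <- "BG_LOW"
  factor(lab, levels = dgrRegions())
}

#' @rdname classifyRoCBG
#' @description `classifyPairs()` classifies every pair of a
#' [PairSet-class] and returns the pair table with a `region` column
#' appended.
#' @param pairs a [PairSet-class].
#' @return `classifyPairs()`: the pair data.frame with a `region` factor
#'   column.
#' @export
classifyPairs <- function(pairs, cfg = RegionConfig()) {
  p <- pairData(pairs)
  p$region <- classifyRoCBG(p$bg, p$roc, cfg)
  p
}

## exact rational compliance test: count/n >= f with f = num/1e4
.meetsMin <- function(count, n, fraction) {
  nd <- .fracNumDen(fraction)
  count * nd["den"] >= nd["num"] * n
}

.withinMax <- function(count, n, fraction) {
  nd <- .fracNumDen(fraction)
  count * nd["den"] <= nd["num"] * n
}

#' Check a pair set against the recommended comparator data distribution
#'
#' Counts pairs per DGR region and tests compliance: every critical region
#' must hold at least `minCriticalFraction` of the pairs (inclusive, exact
#' integer arithmetic, so 3 of 40 meets 7.5% exactly). When all four
#' critical minima are met the neutral fraction is at most 70%
#' automatically. Flagged (irregular-interval) pairs are excluded by
#' default.
#'
#' @param pairs a [PairSet-class] with at least one pair.
#' @param cfg a [RegionConfig-class].
#' @param req a [DistributionRequirements-class].
#' @param includeFlagged include pairs with `valid_interval = FALSE`
#'   (default FALSE).
#' @return A [DistributionReport-class]. The `shortfall` slot gives, per
#'   critical region, the smallest number of additional pairs in that
#'   region that would lift it to the minimum.
#' @examples
#' s <- generateSession(SessionParams(manipulationFraction = 1), seed = 1)
#' distributionReport(computePairs(s))
#' @export
distributionReport <- function(pairs, cfg = RegionConfig(),
                               req = DistributionRequirements(),
                               includeFlagged = FALSE) {
  p <- classifyPairs(pairs, cfg)
  if (!includeFlagged) p <- p[p$valid_interval, , drop = FALSE]
  if (!nrow(p)) stop("no pairs to summarize (all flagged or empty input)")
  counts <- table(p$region)
  counts <- stats::setNames(as.integer(counts[dgrRegions()]), dgrRegions())
  n <- nrow(p)
  crit <- counts[criticalRegions()]
  ok <- vapply(crit, .meetsMin, logical(1), n = n, fraction = req@minCriticalFraction)

  ## smallest x with (c + x) / (n + x) >= f, exact integers
  nd <- .fracNumDen(req@minCriticalFraction)
  short <- vapply(crit, function(c) {
    num <- nd["num"] * n - nd["den"] * c
    if (num <= 0) 0L else as.integer(ceiling(num / (nd["den"] - nd["num"])))
  }, integer(1))

  neutralMax <- {
    nd2 <- .fracNumDen(req@maxNeutralFraction)
    floor(nd2["num"] * n / nd2["den"])
  }
  methods::new("DistributionReport",
    counts = counts,
    fractions = counts / n,
    nTotal = as.integer(n),
    compliant = all(ok),
    shortfall = short,
    neutralExcess = as.integer(max(0, counts[["NEUTRAL"]] - neutralMax))
  )
}

#' Accessors for DistributionReport
#'
#' @param x a [DistributionReport-class].
#' @return `regionCounts()`: named integer vector; `regionFractions()`:
#'   named numeric vector; `isCompliant()`: logical(1).
#' @export
setGeneric("regionCounts", function(x) standardGeneric("regionCounts"))

#' @rdname regionCounts
#' @export
setMethod("regionCounts", "DistributionReport", function(x) x@counts)

#' @rdname regionCounts
#' @export
setGeneric("regionFractions", function(x) standardGeneric("regionFractions"))

#' @rdname regionCounts
#' @export
setMethod("regionFractions", "DistributionReport", function(x) x@fractions)

#' @rdname regionCounts
#' @export
setGeneric("isCompliant", function(x) standardGeneric("isCompliant"))

#' @rdname regionCounts
#' @export
setMethod("isCompliant", "DistributionReport", function(x) x@compliant)

#' Format a fraction as a display percentage
#'
#' One-decimal percentage with half-away-from-zero rounding, matching how
#' study reports print region percentages (e.g. 165/5285 prints as 3.1).
#'
#' @param x numeric vector of fractions in [0, 1].
#' @param digits decimals (default 1).
#' @return numeric vector of percentages.
#' @examples
#' formatPercent(165 / 5285)  # 3.1
#' @export
formatPercent <- function(x, digits = 1) {
  .roundHalfUp(100 * x, digits)
}
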