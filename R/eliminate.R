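## Neutral-region elimination: successively exclude the least critical
## neutral pairs (smallest elliptical distance D from the neutral-region
## center) until every critical region meets its recommended minimum.

#' Elliptical distance from the neutral-region center
#'
#' `D = sqrt((roc / a)^2 + ((bg - bgCenter) / b)^2)` with defaults a = 1
#' mg/(dL*min), b = 115 mg/dL and bgCenter = 185 mg/dL. The locus D = 1 is
#' an ellipse through (roc = 0, bg = 70), (roc = 0, bg = 300) and
#' (roc = +/-1, bg = 185) — it spans the horizontal edges of the neutral
#' region.
#'
#' @param bg numeric vector, glucose in mg/dL.
#' @param roc numeric vector, RoC in mg/(dL*min).
#' @param cfg an [EliminationConfig-class].
#' @return numeric vector of distances D >= 0.
#' @examples
#' distanceD(bg = 70, roc = 0)    # 1
#' distanceD(bg = 185, roc = 0)   # 0
#' distanceD(bg = 185, roc = 1)   # 1
#' @export
distanceD <- function(bg, roc, cfg = EliminationConfig()) {
  stopifnot(is.numeric(bg), is.numeric(roc))
  if (any(!is.finite(bg)) || any(!is.finite(roc))) stop("inputs must be finite")
  sqrt((roc / cfg@a)^2 + ((bg - cfg@bgCenter) / cfg@b)^2)
}

#' Minimal number of exclusions to reach compliance
#'
#' Because only neutral pairs are candidates for exclusion, removing k of
#' them leaves every critical-region count unchanged while shrinking the
#' denominator, so the smallest compliant k has the closed form
#' `max(0, n - floor(c_min * den / num))` where `c_min` is the smallest
#' critical-region count and `num/den` is the required minimum fraction
#' (exact integer arithmetic).
#'
#' @param report a [DistributionReport-class].
#' @param req a [DistributionRequirements-class].
#' @return integer(1): the minimal k, or `Inf` when compliance is
#'   unreachable (some critical region has zero pairs, or the neutral pool
#'   is smaller than the required k).
#' @examples
#' # 28 pairs with 2 in the scarcest critical region: k = 2 (2/26 >= 7.5%)
#' @export
minExclusions <- function(report, req = DistributionRequirements()) {
  counts <- regionCounts(report)
  crit <- counts[criticalRegions()]
  if (any(crit == 0L)) return(Inf)
  n <- report@nTotal
  nd <- .fracNumDen(req@minCriticalFraction)
  cmin <- min(crit)
  k <- max(0L, n - as.integer(floor(cmin * nd["den"] / nd["num"])))
  if (k > counts[["NEUTRAL"]]) return(Inf)
  k
}

#' Eliminate least-critical neutral pairs until the distribution complies
#'
#' Candidates are restricted to the `NEUTRAL` region; each candidate's
#' elliptical distance D is computed and candidates are excluded one at a
#' time in ascending order of D (ties broken deterministically by session,
#' time, then input order), re-evaluating compliance after each exclusion
#' and stopping as soon as every critical region meets its minimum. If any
#' excluded pair has D above the adequacy limit (default 1, the ellipse
#' touching the BG low/high borders), the run completes but is flagged
#' `adequate = FALSE` with a warning: the underlying data set may be
#' inadequate to comply with the recommended distribution. When a critical
#' region has no pairs at all, or the neutral pool is exhausted before
#' compliance, no exclusions are performed and `feasible = FALSE` is
#' returned as a diagnostic.
#'
#' Flagged (irregular-interval) pairs take no part in compliance or
#' elimination by default; they are carried through into the kept set.
#'
#' @param pairs a [PairSet-class] with at least one pair.
#' @param regionCfg a [RegionConfig-class].
#' @param cfg an [EliminationConfig-class].
#' @param req a [DistributionRequirements-class].
#' @param includeFlagged include flagged pairs in compliance and as
#'   candidates (default FALSE).
#' @return An [EliminationResult-class].
#' @examples
#' sessions <- lapply(1:8, function(i)
#'   generateSession(SessionParams(manipulationFraction = 1), seed = i))
#' res <- eliminatePairs(computePairs(sessions))
#' res
#' @export
eliminatePairs <- function(pairs, regionCfg = RegionConfig(),
                           cfg = EliminationConfig(),
                           req = DistributionRequirements(),
                           includeFlagged = FALSE) {
  tab <- classifyPairs(pairs, regionCfg)
  if (!nrow(tab)) stop("empty pair set")
  tab$.row <- seq_len(nrow(tab))
  active <- if (includeFlagged) rep(TRUE, nrow(tab)) else tab$valid_interval
  before <- distributionReport(pairs, regionCfg, req, includeFlagged)

  counts <- regionCounts(before)
  infeasibleResult <- function() {
    methods::new("EliminationResult",
      kept = pairs, excluded = tab[0, , drop = FALSE], k = 0L,
      maxExcludedD = 0, adequate = TRUE, feasible = FALSE,
      before = before, after = before
    )
  }
  if (any(counts[criticalRegions()] == 0L)) {
    warning("a critical region has no pairs; compliance is unreachable")
    return(infeasibleResult())
  }

  cand <- tab[active & tab$region == "NEUTRAL", , drop = FALSE]
  cand$D <- distanceD(cand$bg, cand$roc, cfg)
  ord <- order(cand$D, cand$session_id, cand$time_min, cand$.row)
  cand <- cand[ord, , drop = FALSE]

  nd <- .fracNumDen(req@minCriticalFraction)
  n <- before@nTotal
  crit <- counts[criticalRegions()]
  compliant <- function(k) all(crit * nd["den"] >= nd["num"] * (n - k))

  k <- 0L
  while (!compliant(k)) {
    if (k >= nrow(cand)) {
      warning("neutral pool exhausted before reaching compliance")
      return(infeasibleResult())
    }
    k <- k + 1L
  }

  excluded <- cand[seq_len(k), , drop = FALSE]
  keptTab <- tab[!(tab$.row %in% excluded$.row), , drop = FALSE]
  keptTab$.row <- NULL
  keptTab$region <- NULL
  kept <- PairSet(keptTab)

  maxD <- if (k > 0L) max(excluded$D) else 0
  adequate <- k == 0L || maxD <= cfg@dAdequacyLimit
  if (!adequate) {
    warning(sprintf(
      "excluded pairs with D up to %.3f (> %g): the data set may be inadequate to comply with the recommended distribution",
      maxD, cfg@dAdequacyLimit
    ))
  }
  excluded$.row <- NULL
  methods::new("EliminationResult",
    kept = kept, excluded = excluded, k = k, maxExcludedD = maxD,
    adequate = adequate, feasible = TRUE, before = before,
    after = distributionReport(kept, regionCfg, req, includeFlagged)
  )
}
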