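## RoC-BG pairing: each glucose value after the first in a session is paired
## with the rate of change computed from it and its predecessor, so a series
## of n samples yields n - 1 pairs and there is no pair for time zero.

#' Compute RoC-BG pairs from comparator or CGM series
#'
#' For every sample after the first, the rate of change is the two-point
#' difference quotient `(bg - bg_prev) / dt` with the actual interval `dt`
#' (not the nominal one). Pairs whose interval deviates from the nominal
#' sampling interval by more than `intervalTolerance` minutes are retained
#' but flagged (`valid_interval = FALSE`); by default such pairs are
#' excluded from distribution compliance and elimination. Rows marked
#' `excluded` on the series (safety measurements taken outside the
#' schedule) are dropped before pairing. Pairs never span sessions or
#' subjects.
#'
#' @param x a [ComparatorSeries-class], a [CGMTrace-class], or a list of
#'   them.
#' @param intervalTolerance allowed deviation of `dt` from the nominal
#'   interval in minutes (default 5).
#' @return A [PairSet-class].
#' @examples
#' s <- ComparatorSeries("S01", "V1", time = c(0, 15), glucose = c(100, 130))
#' pairData(computePairs(s))  # one pair, roc = +2
#' @export
setGeneric("computePairs", function(x, intervalTolerance = 5) {
  standardGeneric("computePairs")
})

.pairsFromVectors <- function(subjectId, sessionId, time, glucose,
                              nominal, tolerance) {
  if (length(glucose) < 2L) {
    stop("at least 2 samples are required to compute RoC-BG pairs")
  }
  dt <- diff(time)
  if (any(dt <= 0)) stop("non-positive sampling interval")
  n <- length(glucose)
  data.frame(
    subject_id = subjectId, session_id = sessionId,
    time_min = time[-1L], bg = glucose[-1L],
    roc = diff(glucose) / dt, dt = dt,
    valid_interval = abs(dt - nominal) <= tolerance,
    index = seq_len(n - 1L), stringsAsFactors = FALSE
  )
}

#' @rdname computePairs
#' @export
setMethod("computePairs", "ComparatorSeries", function(x, intervalTolerance = 5) {
  keep <- !x@excluded
  PairSet(.pairsFromVectors(
    x@subjectId, x@sessionId, x@time[keep], x@glucose[keep],
    x@nominalInterval, intervalTolerance
  ))
})

#' @rdname computePairs
#' @export
setMethod("computePairs", "CGMTrace", function(x, intervalTolerance = 5) {
  PairSet(.pairsFromVectors(
    x@subjectId, "cgm", x@time, x@glucose, x@interval, intervalTolerance
  ))
})

#' @rdname computePairs
#' @export
setMethod("computePairs", "list", function(x, intervalTolerance = 5) {
  tabs <- lapply(x, function(s) pairData(computePairs(s, intervalTolerance)))
  tab <- do.call(rbind, tabs)
  tab$index <- seq_len(nrow(tab))
  PairSet(tab)
})

#' Accessors for PairSet
#'
#' `pairData()` returns the underlying data.frame, `nPairs()` the number of
#' pairs.
#'
#' @param x a [PairSet-class].
#' @return A data.frame, or an integer count.
#' @export
setGeneric("pairData", function(x) standardGeneric("pairData"))

#' @rdname pairData
#' @export
setMethod("pairData", "PairSet", function(x) x@pairs)

#' @rdname pairData
#' @export
setGeneric("nPairs", function(x) standardGeneric("nPairs"))

#' @rdname pairData
#' @export
setMethod("nPairs", "PairSet", function(x) nrow(x@pairs))

#' Mean absolute rate of change (MARoC)
#'
#' Mean of `|roc|` over all pairs in the set, in mg/(dL*min). Flagged
#' (irregular-interval) pairs are included unless `onlyValid = TRUE`.
#'
#' @param pairs a [PairSet-class] with at least one pair.
#' @param onlyValid if TRUE, restrict to pairs with `valid_interval`.
#' @return numeric(1), the MARoC.
#' @examples
#' s <- ComparatorSeries("S01", "V1", c(0, 15, 30), c(100, 130, 100))
#' maroc(computePairs(s))  # 2
#' @export
maroc <- function(pairs, onlyValid = FALSE) {
  p <- pairData(pairs)
  if (onlyValid) p <- p[p$valid_interval, , drop = FALSE]
  if (!nrow(p)) stop("cannot compute MARoC of an empty pair set")
  mean(abs(p$roc))
}
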