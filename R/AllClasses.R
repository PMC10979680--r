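## Central S4 containers for comparator and CGM data and for analysis results.
## Canonical internal glucose unit is mg/dL throughout; display conversion to
## mmol/L happens only at formatting time (see units.R).

#' Region labels of the dynamic glucose region (DGR) plot
#'
#' The five mutually exclusive regions of the (BG, RoC) plane: two orange
#' concentration regions (`BG_LOW`, `BG_HIGH`), two red trend-alert regions
#' (`ALERT_LOW`, `ALERT_HIGH`) and the green `NEUTRAL` remainder.
#'
#' @return `dgrRegions()` returns all five labels in canonical order;
#'   `criticalRegions()` returns the four critical (non-neutral) labels.
#' @examples
#' dgrRegions()
#' criticalRegions()
#' @export
dgrRegions <- function() {
  c("BG_LOW", "BG_HIGH", "ALERT_LOW", "ALERT_HIGH", "NEUTRAL")
}

#' @rdname dgrRegions
#' @export
criticalRegions <- function() {
  c("BG_LOW", "BG_HIGH", "ALERT_LOW", "ALERT_HIGH")
}

## physiological plausibility limits for ingested comparator/CGM values
.GLUCOSE_MIN <- 10
.GLUCOSE_MAX <- 600

.checkGlucoseVector <- function(glucose, what = "glucose") {
  if (!is.numeric(glucose)) {
    return(sprintf("%s must be numeric", what))
  }
  if (anyNA(glucose) || any(!is.finite(glucose))) {
    return(sprintf("%s contains missing or non-finite values", what))
  }
  bad <- which(glucose < .GLUCOSE_MIN | glucose > .GLUCOSE_MAX)
  if (length(bad)) {
    return(sprintf(
      "%s outside the physiologically plausible range [%g, %g] mg/dL at position(s) %s",
      what, .GLUCOSE_MIN, .GLUCOSE_MAX,
      paste(utils::head(bad, 5), collapse = ", ")
    ))
  }
  NULL
}

.checkTimeVector <- function(time, n, what = "time") {
  if (!is.numeric(time) || anyNA(time) || any(!is.finite(time))) {
    return(sprintf("%s must be finite numeric", what))
  }
  if (length(time) != n) {
    return(sprintf("%s length does not match glucose length", what))
  }
  if (n > 1 && any(diff(time) <= 0)) {
    bad <- which(diff(time) <= 0)[1L]
    return(sprintf(
      "%s must be strictly increasing (violation between positions %d and %d)",
      what, bad, bad + 1L
    ))
  }
  NULL
}

#' ComparatorSeries: one subject-session of comparator measurements
#'
#' Time-ordered comparator (reference) blood glucose measurements collected
#' during the frequent sampling period (FSP) of one in-clinic session.
#' Glucose is stored in mg/dL; time in minutes from session start.
#'
#' @slot subjectId character(1), opaque subject identifier.
#' @slot sessionId character(1), opaque session identifier.
#' @slot time numeric, strictly increasing sampling times in minutes.
#' @slot glucose numeric, glucose concentrations in mg/dL, each in [10, 600].
#' @slot nominalInterval numeric(1), nominal sampling interval in minutes
#'   (default 15).
#' @slot excluded logical, rows flagged by the caller (e.g. safety
#'   measurements outside the schedule) that are dropped before RoC pairing.
#'
#' @seealso [ComparatorSeries()], [computePairs()]
#' @export
setClass("ComparatorSeries",
  representation(
    subjectId = "character",
    sessionId = "character",
    time = "numeric",
    glucose = "numeric",
    nominalInterval = "numeric",
    excluded = "logical"
  ),
  prototype(nominalInterval = 15)
)

setValidity("ComparatorSeries", function(object) {
  msgs <- character()
  if (length(object@subjectId) != 1L || is.na(object@subjectId)) {
    msgs <- c(msgs, "subjectId must be a single non-missing string")
  }
  if (length(object@sessionId) != 1L || is.na(object@sessionId)) {
    msgs <- c(msgs, "sessionId must be a single non-missing string")
  }
  m <- .checkGlucoseVector(object@glucose)
  if (!is.null(m)) msgs <- c(msgs, m)
  m <- .checkTimeVector(object@time, length(object@glucose))
  if (!is.null(m)) msgs <- c(msgs, m)
  if (length(object@nominalInterval) != 1L || object@nominalInterval <= 0) {
    msgs <- c(msgs, "nominalInterval must be a single positive number")
  }
  if (length(object@excluded) != length(object@glucose)) {
    msgs <- c(msgs, "excluded must have one flag per sample")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a ComparatorSeries
#'
#' @param subjectId,sessionId opaque identifiers.
#' @param time numeric vector of sampling times in minutes from session
#'   start, strictly increasing.
#' @param glucose numeric vector of glucose values in mg/dL.
#' @param nominalInterval nominal sampling interval in minutes (default 15).
#' @param excluded optional logical vector marking rows to drop before
#'   pairing (defaults to all `FALSE`).
#' @return A [ComparatorSeries-class] object.
#' @examples
#' s <- ComparatorSeries("S01", "V1", time = c(0, 15, 30),
#'                       glucose = c(100, 130, 160))
#' s
#' @export
ComparatorSeries <- function(subjectId, sessionId, time, glucose,
                             nominalInterval = 15, excluded = NULL) {
  if (is.null(excluded)) excluded <- rep(FALSE, length(glucose))
  methods::new("ComparatorSeries",
    subjectId = as.character(subjectId),
    sessionId = as.character(sessionId),
    time = as.numeric(time),
    glucose = as.numeric(glucose),
    nominalInterval = as.numeric(nominalInterval),
    excluded = as.logical(excluded)
  )
}

#' CGMTrace: a continuous glucose monitoring sensor trace
#'
#' Time-ordered sensor glucose readings for one subject, typically sampled
#' every 5 minutes. Gaps are allowed provided they are whole multiples of the
#' sampling interval; analysis functions break runs at gaps.
#'
#' @slot subjectId character(1) subject identifier.
#' @slot time numeric, strictly increasing times in minutes.
#' @slot glucose numeric, sensor glucose in mg/dL.
#' @slot interval numeric(1), nominal sampling interval in minutes
#'   (default 5).
#' @seealso [CGMTrace()], [detectEpisodes()]
#' @export
setClass("CGMTrace",
  representation(
    subjectId = "character",
    time = "numeric",
    glucose = "numeric",
    interval = "numeric"
  ),
  prototype(interval = 5)
)

setValidity("CGMTrace", function(object) {
  msgs <- character()
  if (length(object@subjectId) != 1L || is.na(object@subjectId)) {
    msgs <- c(msgs, "subjectId must be a single non-missing string")
  }
  m <- .checkGlucoseVector(object@glucose)
  if (!is.null(m)) msgs <- c(msgs, m)
  m <- .checkTimeVector(object@time, length(object@glucose))
  if (!is.null(m)) msgs <- c(msgs, m)
  if (length(object@interval) != 1L || object@interval <= 0) {
    msgs <- c(msgs, "interval must be a single positive number")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a CGMTrace
#'
#' @param subjectId opaque subject identifier.
#' @param time numeric vector of times in minutes, strictly increasing.
#' @param glucose numeric vector of sensor glucose values in mg/dL.
#' @param interval nominal sampling interval in minutes (default 5).
#' @return A [CGMTrace-class] object.
#' @export
CGMTrace <- function(subjectId, time, glucose, interval = 5) {
  methods::new("CGMTrace",
    subjectId = as.character(subjectId),
    time = as.numeric(time),
    glucose = as.numeric(glucose),
    interval = as.numeric(interval)
  )
}

.PAIR_COLUMNS <- c(
  "subject_id", "session_id", "time_min", "bg", "roc", "dt",
  "valid_interval", "index"
)

#' PairSet: RoC-BG pairs with provenance
#'
#' Each row pairs a comparator glucose value (`bg`, mg/dL) with the rate of
#' change (`roc`, mg/(dL*min)) computed from it and its predecessor in the
#' same session, following the convention that the first sample of a series
#' yields no pair. `dt` is the actual interval to the preceding sample and
#' `valid_interval` flags pairs whose interval is within tolerance of the
#' nominal sampling interval.
#'
#' @slot pairs data.frame with columns `subject_id`, `session_id`,
#'   `time_min`, `bg`, `roc`, `dt`, `valid_interval`, `index`.
#' @seealso [computePairs()], [classifyPairs()], [maroc()]
#' @export
setClass("PairSet", representation(pairs = "data.frame"))

setValidity("PairSet", function(object) {
  missing <- setdiff(.PAIR_COLUMNS, names(object@pairs))
  if (length(missing)) {
    return(paste("pairs is missing column(s):", paste(missing, collapse = ", ")))
  }
  p <- object@pairs
  if (nrow(p)) {
    if (any(!is.finite(p$bg)) || any(!is.finite(p$roc))) {
      return("bg and roc must be finite")
    }
    if (any(p$dt <= 0)) return("dt must be positive")
    if (!is.logical(p$valid_interval)) return("valid_interval must be logical")
  }
  TRUE
})

#' Construct a PairSet from a data.frame of pairs
#'
#' Usually produced by [computePairs()]; the constructor is exported for
#' round-tripping pair tables through CSV.
#'
#' @param pairs data.frame with the columns documented in
#'   [PairSet-class].
#' @return A [PairSet-class] object.
#' @export
PairSet <- function(pairs) {
  rownames(pairs) <- NULL
  methods::new("PairSet", pairs = pairs)
}

#' DistributionReport: per-region counts and compliance
#'
#' Result of checking a [PairSet-class] against the recommended comparator
#' data distribution (each critical region at least 7.5% of pairs, neutral
#' region at most 70%).
#'
#' @slot counts named integer, pairs per region (all five regions).
#' @slot fractions named numeric, counts / nTotal.
#' @slot nTotal integer(1), total pairs considered.
#' @slot compliant logical(1), TRUE iff every critical-region fraction meets
#'   the minimum (exact rational comparison).
#' @slot shortfall named integer, per critical region the smallest number of
#'   additional pairs in that region that would lift it to the minimum
#'   (0 when already met).
#' @slot neutralExcess integer(1), number of neutral pairs above the
#'   allowed maximum neutral fraction (0 when within the limit).
#' @seealso [distributionReport()]
#' @export
setClass("DistributionReport",
  representation(
    counts = "integer",
    fractions = "numeric",
    nTotal = "integer",
    compliant = "logical",
    shortfall = "integer",
    neutralExcess = "integer"
  )
)

setValidity("DistributionReport", function(object) {
  if (!identical(names(object@counts), dgrRegions())) {
    return("counts must be named by the five DGR regions in canonical order")
  }
  if (sum(object@counts) != object@nTotal) {
    return("counts must sum to nTotal")
  }
  if (abs(sum(object@fractions) - 1) > 1e-12) {
    return("fractions must sum to 1")
  }
  TRUE
})

#' EliminationResult: outcome of the neutral-region elimination procedure
#'
#' @slot kept [PairSet-class] of retained pairs (original order preserved).
#' @slot excluded data.frame of excluded neutral pairs with their elliptical
#'   distance `D`, sorted ascending by `D`.
#' @slot k integer(1), number of excluded pairs.
#' @slot maxExcludedD numeric(1), largest `D` among excluded pairs (0 when
#'   none).
#' @slot adequate logical(1), FALSE when any excluded pair had `D` above the
#'   adequacy limit, indicating the data set may be inadequate.
#' @slot feasible logical(1), FALSE when compliance is unreachable (a
#'   critical region is empty, or the neutral pool is exhausted); in that
#'   case no exclusions are performed.
#' @slot before,after [DistributionReport-class] before and after
#'   elimination (`after` equals `before` when infeasible).
#' @seealso [eliminatePairs()]
#' @export
setClass("EliminationResult",
  representation(
    kept = "PairSet",
    excluded = "data.frame",
    k = "integer",
    maxExcludedD = "numeric",
    adequate = "logical",
    feasible = "logical",
    before = "DistributionReport",
    after = "DistributionReport"
  )
)

#' StudyReport: pooled study-level characterization
#'
#' Machine-readable summary tying together per-session and pooled
#' distribution reports, the mean absolute rate of change, and (optionally)
#' an elimination summary.
#'
#' @slot sessions list of per-session summaries (one element per
#'   subject-session).
#' @slot pooled [DistributionReport-class] over all sessions.
#' @slot maroc numeric(1), mean absolute RoC in mg/(dL*min).
#' @slot elimination an [EliminationResult-class] or NULL.
#' @slot config list echoing the configuration used.
#' @slot version character(1), report schema version.
#' @seealso [runReport()], [writeStudyReport()]
#' @export
setClass("StudyReport",
  representation(
    sessions = "list",
    pooled = "DistributionReport",
    maroc = "numeric",
    elimination = "ANY",
    config = "list",
    version = "character"
  )
)
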