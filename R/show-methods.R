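## show() methods

#' @describeIn ComparatorSeries-class compact display
#' @param object the object to display.
#' @export
setMethod("show", "ComparatorSeries", function(object) {
  cat(sprintf(
    "ComparatorSeries %s/%s: %d samples over %.0f min (nominal %g-min grid)\n",
    object@subjectId, object@sessionId, length(object@glucose),
    diff(range(object@time)), object@nominalInterval
  ))
  cat(sprintf(
    "  glucose %.0f-%.0f mg/dL; %d row(s) flagged for exclusion\n",
    min(object@glucose), max(object@glucose), sum(object@excluded)
  ))
  invisible(NULL)
})

#' @describeIn CGMTrace-class compact display
#' @param object the object to display.
#' @export
setMethod("show", "CGMTrace", function(object) {
  cat(sprintf(
    "CGMTrace %s: %d samples over %.0f min (%g-min interval)\n",
    object@subjectId, length(object@glucose),
    diff(range(object@time)), object@interval
  ))
  invisible(NULL)
})

#' @describeIn PairSet-class compact display
#' @param object the object to display.
#' @export
setMethod("show", "PairSet", function(object) {
  p <- object@pairs
  cat(sprintf(
    "PairSet: %d RoC-BG pairs from %d session(s); %d flagged interval(s)\n",
    nrow(p), length(unique(paste(p$subject_id, p$session_id))),
    sum(!p$valid_interval)
  ))
  if (nrow(p)) {
    cat(sprintf(
      "  MARoC %.2f mg/(dL*min); bg %.0f-%.0f mg/dL\n",
      mean(abs(p$roc)), min(p$bg), max(p$bg)
    ))
  }
  invisible(NULL)
})

#' @describeIn DistributionReport-class compact display
#' @param object the object to display.
#' @export
setMethod("show", "DistributionReport", function(object) {
  cat(sprintf(
    "DistributionReport: n = %d, %s\n", object@nTotal,
    if (object@compliant) "COMPLIANT" else "NON-COMPLIANT"
  ))
  for (r in dgrRegions()) {
    cat(sprintf(
      "  %-10s %5d  (%5.1f%%)%s\n", r, object@counts[[r]],
      formatPercent(object@fractions[[r]]),
      if (r %in% criticalRegions() && object@shortfall[[r]] > 0) {
        sprintf("  short by %d", object@shortfall[[r]])
      } else ""
    ))
  }
  invisible(NULL)
})

#' @describeIn EliminationResult-class compact display
#' @param object the object to display.
#' @export
setMethod("show", "EliminationResult", function(object) {
  if (!object@feasible) {
    cat("EliminationResult: INFEASIBLE (no exclusions performed)\n")
    return(invisible(NULL))
  }
  cat(sprintf(
    "EliminationResult: excluded %d of %d neutral-region pairs (%.1f%% of all)\n",
    object@k, object@before@counts[["NEUTRAL"]],
    formatPercent(object@k / object@before@nTotal)
  ))
  cat(sprintf(
    "  max excluded D = %.3f; adequate = %s; kept set %s\n",
    object@maxExcludedD, object@adequate,
    if (object@after@compliant) "COMPLIANT" else "NON-COMPLIANT"
  ))
  invisible(NULL)
})

#' @describeIn StudyReport-class compact display
#' @param object the object to display.
#' @export
setMethod("show", "StudyReport", function(object) {
  cat(sprintf(
    "StudyReport (schema %s): %d session(s), pooled n = %d, MARoC %.2f mg/(dL*min)\n",
    object@version, length(object@sessions), object@pooled@nTotal, object@maroc
  ))
  methods::show(object@pooled)
  if (!is.null(object@elimination)) {
    methods::show(object@elimination)
  }
  invisible(NULL)
})
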