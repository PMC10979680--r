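## Study-level reporting: per-session and pooled distribution reports,
## MARoC, optional elimination, JSON export against a bundled schema.

.REPORT_VERSION <- "1.0"

.reportToList <- function(rep) {
  list(
    n = rep@nTotal,
    counts = as.list(rep@counts),
    fractions = as.list(round(rep@fractions, 6)),
    percent_display = as.list(formatPercent(rep@fractions)),
    compliant = rep@compliant,
    shortfall = as.list(rep@shortfall),
    neutral_excess = rep@neutralExcess
  )
}

#' Run the full comparator characterization pipeline
#'
#' Reads (or accepts) comparator series, computes RoC-BG pairs per
#' session, classifies them, builds per-session and pooled distribution
#' reports and the MARoC, and optionally runs the neutral-region
#' elimination when the pooled distribution is non-compliant.
#'
#' @param input path to a comparator CSV, a list of
#'   [ComparatorSeries-class], or a single series.
#' @param regionCfg a [RegionConfig-class].
#' @param req a [DistributionRequirements-class].
#' @param elimCfg an [EliminationConfig-class].
#' @param eliminate run [eliminatePairs()] when the pooled report is
#'   non-compliant (default FALSE).
#' @param intervalTolerance passed to [computePairs()].
#' @return A [StudyReport-class].
#' @examples
#' sessions <- lapply(1:6, function(i)
#'   generateSession(SessionParams(manipulationFraction = 1), seed = i,
#'                   subjectId = sprintf("P%02d", i)))
#' runReport(sessions)
#' @export
runReport <- function(input, regionCfg = RegionConfig(),
                      req = DistributionRequirements(),
                      elimCfg = EliminationConfig(),
                      eliminate = FALSE, intervalTolerance = 5) {
  series <- if (is.character(input)) {
    readComparatorCSV(input)
  } else if (methods::is(input, "ComparatorSeries")) {
    list(input)
  } else {
    input
  }
  pairsBySession <- lapply(series, computePairs, intervalTolerance = intervalTolerance)
  pooled <- computePairs(series, intervalTolerance = intervalTolerance)

  sessions <- lapply(seq_along(series), function(i) {
    s <- series[[i]]
    rep <- distributionReport(pairsBySession[[i]], regionCfg, req)
    list(
      subject_id = s@subjectId, session_id = s@sessionId,
      maroc = maroc(pairsBySession[[i]]),
      report = .reportToList(rep)
    )
  })

  pooledRep <- distributionReport(pooled, regionCfg, req)
  elim <- NULL
  if (eliminate && !pooledRep@compliant) {
    elim <- eliminatePairs(pooled, regionCfg, elimCfg, req)
  }

  methods::new("StudyReport",
    sessions = sessions,
    pooled = pooledRep,
    maroc = maroc(pooled),
    elimination = elim,
    config = list(
      region = list(
        bg_low = regionCfg@bgLow, bg_high = regionCfg@bgHigh,
        hypo_target = regionCfg@hypoTarget,
        hyper_target = regionCfg@hyperTarget,
        horizon_min = regionCfg@horizon,
        alert_low_roc = regionCfg@alertLowRoC,
        alert_high_roc = regionCfg@alertHighRoC
      ),
      requirements = list(
        min_critical_fraction = req@minCriticalFraction,
        max_neutral_fraction = req@maxNeutralFraction
      ),
      elimination = list(
        a = elimCfg@a, b = elimCfg@b, bg_center = elimCfg@bgCenter,
        d_adequacy_limit = elimCfg@dAdequacyLimit
      ),
      interval_tolerance_min = intervalTolerance
    ),
    version = .REPORT_VERSION
  )
}

#' Export a StudyReport as JSON
#'
#' The JSON layout is versioned (`schema_version`) and follows the schema
#' bundled at `system.file("schema", "study_report_schema.json",
#' package = "dgrtools")`; [validateStudyReportJSON()] checks a written
#' file against it.
#'
#' @param report a [StudyReport-class].
#' @param path output path.
#' @return The path, invisibly.
#' @export
writeStudyReport <- function(report, path) {
  elim <- report@elimination
  out <- list(
    schema_version = report@version,
    software = paste0("dgrtools ", as.character(utils::packageVersion("dgrtools"))),
    n_sessions = length(report@sessions),
    maroc_mgdl_min = report@maroc,
    pooled = .reportToList(report@pooled),
    sessions = report@sessions,
    elimination = if (is.null(elim)) NULL else list(
      feasible = elim@feasible,
      k = elim@k,
      n_total = elim@before@nTotal,
      pct_excluded = formatPercent(elim@k / elim@before@nTotal),
      max_excluded_d = elim@maxExcludedD,
      adequate = elim@adequate,
      before = .reportToList(elim@before),
      after = .reportToList(elim@after)
    ),
    config = report@config
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname writeStudyReport
#' @description `validateStudyReportJSON()` re-reads a written report and
#' checks required fields and types against the bundled schema
#' description.
#' @param jsonPath path of a written report.
#' @return `validateStudyReportJSON()` returns TRUE invisibly, or stops
#'   with the first violation.
#' @export
validateStudyReportJSON <- function(jsonPath) {
  schema <- jsonlite::read_json(
    system.file("schema", "study_report_schema.json", package = "dgrtools")
  )
  doc <- jsonlite::read_json(jsonPath)
  for (f in names(schema$required)) {
    if (is.null(doc[[f]])) stop("report is missing required field: ", f)
    want <- schema$required[[f]]
    got <- class(doc[[f]])[1L]
    okType <- switch(want,
      string = got == "character",
      number = got %in% c("numeric", "integer"),
      object = got == "list",
      array = got == "list",
      TRUE
    )
    if (!okType) {
      stop(sprintf("field %s: expected %s, got %s", f, want, got))
    }
  }
  for (f in c("n", "counts", "fractions", "compliant")) {
    if (is.null(doc$pooled[[f]])) {
      stop("pooled report is missing required field: ", f)
    }
  }
  invisible(TRUE)
}
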