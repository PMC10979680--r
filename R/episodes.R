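## Hypo-/hyperglycemic episode detection in CGM traces, pre-episode
## qualification, and AGP-style aligned percentile summaries.

## dt must be positive multiples of the nominal interval; a dt > interval is
## a gap (breaks runs), anything else is an error
.traceSteps <- function(trace) {
  dt <- diff(trace@time)
  mult <- dt / trace@interval
  if (any(abs(mult - round(mult)) > 1e-6) || any(mult < 1 - 1e-6)) {
    stop(
      "non-uniform sampling interval without explicit gap markers: ",
      "time steps must be positive whole multiples of the sampling interval"
    )
  }
  round(mult)
}

#' Detect hypo-/hyperglycemic episodes in a CGM trace
#'
#' An episode is a maximal run of consecutive readings strictly below the
#' hypo threshold (70 mg/dL) or strictly above the hyper threshold
#' (250 mg/dL), with runs broken at sampling gaps. The episode duration is
#' the time spanned between its first and last beyond-threshold sample
#' (`(run length - 1) * interval` under the default `"span"` convention).
#' Episodes shorter than `minDuration` (15 min) or longer than
#' `maxDuration` (120 min) are reported but flagged `included = FALSE`
#' with an exclusion reason; successive episodes are separated by at least
#' one in-range sample or a gap.
#'
#' @param trace a [CGMTrace-class] with uniform sampling (gaps allowed as
#'   whole multiples of the interval).
#' @param cfg an [EpisodeConfig-class].
#' @param kind `"hypo"` or `"hyper"`.
#' @param qualify also apply the pre-episode qualification criterion to
#'   each episode (default TRUE), see [qualifyEpisode()].
#' @return A data.frame with one row per detected episode: `subject_id`,
#'   `kind`, `start_idx`, `end_idx`, `start_time`, `end_time`,
#'   `duration`, `n_samples`, `included`, `exclusion_reason`, and (when
#'   `qualify`) `qualified`, `disqualification_reason`.
#' @examples
#' tr <- CGMTrace("S1", seq(0, 115, 5),
#'                c(rep(100, 12), rep(60, 4), rep(100, 8)))
#' detectEpisodes(tr, kind = "hypo")
#' @export
detectEpisodes <- function(trace, cfg = EpisodeConfig(),
                           kind = c("hypo", "hyper"), qualify = TRUE) {
  kind <- match.arg(kind)
  stopifnot(methods::is(trace, "CGMTrace"))
  g <- trace@glucose
  n <- length(g)
  steps <- if (n > 1L) .traceSteps(trace) else integer(0)

  beyond <- if (kind == "hypo") g < cfg@hypoThreshold else g > cfg@hyperThreshold
  ## break runs at gaps: a run continues only across dt == interval
  runId <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    newRun <- !beyond[i] ||
      i == 1L || !beyond[i - 1L] || steps[i - 1L] != 1L
    if (beyond[i] && newRun) cur <- cur + 1L
    runId[i] <- if (beyond[i]) cur else 0L
  }
  if (cur == 0L) {
    out <- data.frame(
      subject_id = character(), kind = character(), start_idx = integer(),
      end_idx = integer(), start_time = numeric(), end_time = numeric(),
      duration = numeric(), n_samples = integer(), included = logical(),
      exclusion_reason = character(), stringsAsFactors = FALSE
    )
    if (qualify) {
      out$qualified <- logical()
      out$disqualification_reason <- character()
    }
    return(out)
  }

  eps <- lapply(seq_len(cur), function(r) {
    idx <- which(runId == r)
    len <- length(idx)
    dur <- if (cfg@durationConvention == "span") {
      trace@time[idx[len]] - trace@time[idx[1L]]
    } else {
      len * trace@interval
    }
    reason <- ""
    if (dur < cfg@minDuration) reason <- "too_short"
    if (dur > cfg@maxDuration) reason <- "too_long"
    data.frame(
      subject_id = trace@subjectId, kind = kind,
      start_idx = idx[1L], end_idx = idx[len],
      start_time = trace@time[idx[1L]], end_time = trace@time[idx[len]],
      duration = dur, n_samples = len,
      included = reason == "", exclusion_reason = reason,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, eps)
  if (qualify) {
    q <- lapply(seq_len(nrow(out)), function(i) qualifyEpisode(out[i, ], trace, cfg))
    out$qualified <- vapply(q, `[[`, logical(1), "qualified")
    out$disqualification_reason <- vapply(q, `[[`, character(1), "reason")
  }
  out
}

#' Pre-episode qualification of a detected episode
#'
#' An episode qualifies when the full lookback window (default 60 min)
#' before its start is observed without gaps and the trace within it is on
#' the in-range side of the threshold (>= 70 mg/dL before a hypo episode,
#' <= 250 mg/dL before a hyper episode) and changes monotonically toward
#' the episode: successive differences <= 0 (hypo) or >= 0 (hyper),
#' non-strict, so flat segments are allowed. A missing or gapped lookback
#' disqualifies with reason `"incomplete_lookback"`.
#'
#' @param episode one row of the data.frame returned by
#'   [detectEpisodes()].
#' @param trace the [CGMTrace-class] the episode was detected in.
#' @param cfg an [EpisodeConfig-class].
#' @return A list with elements `qualified` (logical) and `reason`
#'   (character, `""` when qualified).
#' @export
qualifyEpisode <- function(episode, trace, cfg = EpisodeConfig()) {
  need <- cfg@lookback / trace@interval
  if (abs(need - round(need)) > 1e-9) {
    stop("lookback must be a multiple of the trace sampling interval")
  }
  need <- round(need)
  startIdx <- episode$start_idx
  if (startIdx <= need) {
    return(list(qualified = FALSE, reason = "incomplete_lookback"))
  }
  idx <- (startIdx - need):startIdx # lookback window plus episode start
  t <- trace@time[idx]
  if (any(abs(diff(t) - trace@interval) > 1e-9)) {
    return(list(qualified = FALSE, reason = "incomplete_lookback"))
  }
  pre <- trace@glucose[idx[-length(idx)]]
  if (episode$kind == "hypo") {
    if (any(pre < cfg@hypoThreshold)) {
      return(list(qualified = FALSE, reason = "lookback_below_threshold"))
    }
    if (any(diff(pre) > 0)) {
      return(list(qualified = FALSE, reason = "not_monotone"))
    }
  } else {
    if (any(pre > cfg@hyperThreshold)) {
      return(list(qualified = FALSE, reason = "lookback_above_threshold"))
    }
    if (any(diff(pre) < 0)) {
      return(list(qualified = FALSE, reason = "not_monotone"))
    }
  }
  list(qualified = TRUE, reason = "")
}

#' Aligned percentile summary of episode traces (AGP style)
#'
#' Aligns CGM traces at episode start (offset 0 = first beyond-threshold
#' sample) and computes per-offset percentiles (5th, 25th, 50th, 75th,
#' 95th by default) over the available traces, from `window[1]` to
#' `window[2]` minutes. Percentiles use linear interpolation between order
#' statistics (quantile type 6, which clamps extreme percentiles to the
#' extreme order statistics for small n). Offsets observed in fewer than
#' `minTraces` traces are masked (`NA`).
#'
#' @param episodes a data.frame as returned by [detectEpisodes()]
#'   (possibly pooled over traces); only rows with `included` (and, when
#'   present, `qualified`) are used unless `onlyQualified = FALSE`.
#' @param traces a named list of [CGMTrace-class] objects keyed by
#'   `subject_id`, or a single trace.
#' @param window numeric(2), offsets in minutes relative to episode start
#'   (default c(-60, 60)).
#' @param probs percentile levels (default c(.05, .25, .50, .75, .95)).
#' @param minTraces minimum traces per offset (default 1).
#' @param onlyQualified restrict to qualified episodes (default TRUE).
#' @return A data.frame with columns `offset_min`, one `p<level>` column
#'   per percentile, and `n` (traces contributing at that offset).
#' @export
alignedSummary <- function(episodes, traces, window = c(-60, 60),
                           probs = c(0.05, 0.25, 0.50, 0.75, 0.95),
                           minTraces = 1, onlyQualified = TRUE) {
  if (methods::is(traces, "CGMTrace")) {
    traces <- stats::setNames(list(traces), traces@subjectId)
  }
  use <- episodes[episodes$included, , drop = FALSE]
  if (onlyQualified && "qualified" %in% names(use)) {
    use <- use[use$qualified, , drop = FALSE]
  }
  if (!nrow(use)) stop("no (qualified) episodes to summarize")
  interval <- traces[[1L]]@interval
  offsets <- seq(window[1L], window[2L], by = interval)

  vals <- sapply(seq_len(nrow(use)), function(i) {
    tr <- traces[[use$subject_id[i]]]
    if (is.null(tr)) stop("no trace for subject ", use$subject_id[i])
    at <- use$start_time[i] + offsets
    idx <- match(round(at / interval), round(tr@time / interval))
    tr@glucose[idx]
  })
  vals <- matrix(vals, nrow = length(offsets))

  nAvail <- rowSums(!is.na(vals))
  qs <- t(apply(vals, 1L, function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) return(rep(NA_real_, length(probs)))
    stats::quantile(v, probs = probs, type = 6, names = FALSE)
  }))
  qs[nAvail < minTraces, ] <- NA_real_
  out <- data.frame(offset_min = offsets, qs, n = nAvail)
  names(out) <- c("offset_min", paste0("p", probs * 100), "n")
  out
}

## centered moving average, window w (odd); shrinks symmetrically at edges
.movingAverage <- function(x, w) {
  if (w <= 1L) return(x)
  half <- (w - 1L) %/% 2L
  n <- length(x)
  vapply(seq_len(n), function(i) {
    j <- max(1L, i - half):min(n, i + half)
    mean(x[j])
  }, numeric(1))
}

#' Project an aligned summary curve onto the DGR plane
#'
#' Computes the RoC between consecutive points of one percentile curve of
#' an aligned summary (pairing each value with the RoC from its
#' predecessor) and optionally smooths bg and roc with a centered moving
#' average, yielding a (bg, roc) curve suitable for overlay on the DGR
#' plot.
#'
#' @param summary a data.frame from [alignedSummary()].
#' @param percentile name of the percentile column (default `"p50"`).
#' @param smoothWindow centered moving-average window in points (odd,
#'   default 3; 1 disables smoothing).
#' @param range offsets (minutes) to project, default `c(-60, 0)` — from
#'   the start of the lookback to the episode start.
#' @return A data.frame with columns `offset_min`, `bg`, `roc`.
#' @export
projectSummaryToDGR <- function(summary, percentile = "p50",
                                smoothWindow = 3, range = c(-60, 0)) {
  if (!percentile %in% names(summary)) {
    stop("percentile column not present: ", percentile)
  }
  s <- summary[summary$offset_min >= range[1L] & summary$offset_min <= range[2L], ]
  bg <- s[[percentile]]
  t <- s$offset_min
  roc <- c(NA_real_, diff(bg) / diff(t))
  out <- data.frame(
    offset_min = t[-1L],
    bg = .movingAverage(bg[-1L], smoothWindow),
    roc = .movingAverage(roc[-1L], smoothWindow)
  )
  out
}
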