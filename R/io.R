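## CSV readers/writers for comparator and CGM tables.
##
## Comparator CSV columns: subject_id, session_id, time_min (minutes from
## session start) OR timestamp (ISO-8601), glucose, unit in {mg/dL, mmol/L},
## optional logical column exclude. CGM CSV: subject_id, time_min|timestamp,
## glucose, unit. UTF-8, comma-separated, header mandatory. Units are
## canonicalized to mg/dL on ingest; timestamps to minutes from the first
## sample of each group.

.requireColumns <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop(sprintf(
      "%s: missing required column(s): %s",
      path, paste(missing, collapse = ", ")
    ), call. = FALSE)
  }
}

.parseTimes <- function(df, path) {
  if ("time_min" %in% names(df)) {
    t <- suppressWarnings(as.numeric(df$time_min))
    if (anyNA(t)) {
      stop(sprintf(
        "%s: unparseable time_min at data row %d",
        path, which(is.na(t))[1L]
      ), call. = FALSE)
    }
    return(t)
  }
  if ("timestamp" %in% names(df)) {
    ts <- as.POSIXct(df$timestamp,
      tz = "UTC",
      tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS", "%Y-%m-%d %H:%M")
    )
    if (anyNA(ts)) {
      stop(sprintf(
        "%s: unparseable timestamp at data row %d",
        path, which(is.na(ts))[1L]
      ), call. = FALSE)
    }
    return(as.numeric(ts)) # seconds; converted per group below
  }
  stop(sprintf("%s: need a time_min or timestamp column", path), call. = FALSE)
}

.parseGlucose <- function(df, path) {
  g <- suppressWarnings(as.numeric(df$glucose))
  if (anyNA(g)) {
    stop(sprintf(
      "%s: unparseable glucose at data row %d",
      path, which(is.na(g))[1L]
    ), call. = FALSE)
  }
  unit <- .normGlucoseUnit(df$unit)
  ifelse(unit == "mg/dL", g, g * MGDL_PER_MMOLL)
}

#' Read and write comparator measurement tables
#'
#' @description `readComparatorCSV()` reads a comparator CSV (columns
#' `subject_id`, `session_id`, `time_min` or ISO-8601 `timestamp`,
#' `glucose`, `unit`, optional logical `exclude`), canonicalizes all values
#' to mg/dL, groups rows by (subject, session), and returns one
#' [ComparatorSeries-class] per group. Rows may mix units.
#' `writeComparatorCSV()` writes the canonical form back; a write-read
#' round trip is lossless.
#'
#' @param path file path.
#' @param nominalInterval nominal sampling interval passed to each series
#'   (minutes, default 15).
#' @return `readComparatorCSV()`: a named list of
#'   [ComparatorSeries-class] objects (names `subject/session`);
#'   `writeComparatorCSV()`: the path, invisibly.
#' @export
readComparatorCSV <- function(path, nominalInterval = 15) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .requireColumns(df, c("subject_id", "session_id", "glucose", "unit"), path)
  time <- .parseTimes(df, path)
  glucose <- .parseGlucose(df, path)
  absolute <- !("time_min" %in% names(df))
  exclude <- if ("exclude" %in% names(df)) as.logical(df$exclude) else rep(FALSE, nrow(df))
  exclude[is.na(exclude)] <- FALSE

  key <- paste(df$subject_id, df$session_id, sep = "/")
  out <- list()
  for (k in unique(key)) {
    i <- which(key == k)
    i <- i[order(time[i])]
    t <- time[i]
    if (absolute) t <- (t - t[1L]) / 60
    dup <- which(diff(t) <= 0)
    if (length(dup)) {
      stop(sprintf(
        "%s: non-increasing time within group %s at data row %d",
        path, k, i[dup[1L] + 1L]
      ), call. = FALSE)
    }
    out[[k]] <- ComparatorSeries(
      subjectId = df$subject_id[i[1L]], sessionId = df$session_id[i[1L]],
      time = t, glucose = glucose[i],
      nominalInterval = nominalInterval, excluded = exclude[i]
    )
  }
  out
}

#' @rdname readComparatorCSV
#' @param series a [ComparatorSeries-class] or list thereof.
#' @export
writeComparatorCSV <- function(series, path) {
  if (methods::is(series, "ComparatorSeries")) series <- list(series)
  rows <- lapply(series, function(s) {
    data.frame(
      subject_id = s@subjectId, session_id = s@sessionId,
      time_min = s@time, glucose = s@glucose, unit = "mg/dL",
      exclude = s@excluded, stringsAsFactors = FALSE
    )
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write CGM trace tables
#'
#' CGM CSV columns: `subject_id`, `time_min` or ISO-8601 `timestamp`,
#' `glucose`, `unit`. One [CGMTrace-class] is returned per subject.
#'
#' @param path file path.
#' @param interval nominal sampling interval in minutes (default 5).
#' @return `readCGMCSV()`: a named list of [CGMTrace-class] objects;
#'   `writeCGMCSV()`: the path, invisibly.
#' @export
readCGMCSV <- function(path, interval = 5) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .requireColumns(df, c("subject_id", "glucose", "unit"), path)
  time <- .parseTimes(df, path)
  glucose <- .parseGlucose(df, path)
  absolute <- !("time_min" %in% names(df))

  out <- list()
  for (k in unique(df$subject_id)) {
    i <- which(df$subject_id == k)
    i <- i[order(time[i])]
    t <- time[i]
    if (absolute) t <- (t - t[1L]) / 60
    dup <- which(diff(t) <= 0)
    if (length(dup)) {
      stop(sprintf(
        "%s: non-increasing time for subject %s at data row %d",
        path, k, i[dup[1L] + 1L]
      ), call. = FALSE)
    }
    out[[k]] <- CGMTrace(
      subjectId = k, time = t, glucose = glucose[i], interval = interval
    )
  }
  out
}

#' @rdname readCGMCSV
#' @param traces a [CGMTrace-class] or list thereof.
#' @export
writeCGMCSV <- function(traces, path) {
  if (methods::is(traces, "CGMTrace")) traces <- list(traces)
  rows <- lapply(traces, function(s) {
    data.frame(
      subject_id = s@subjectId, time_min = s@time,
      glucose = s@glucose, unit = "mg/dL", stringsAsFactors = FALSE
    )
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write RoC-BG pair tables
#'
#' Pair CSV columns: `subject_id`, `session_id`, `time_min`, `bg_mgdl`,
#' `roc_mgdl_min`, `dt_min`, `valid_interval`.
#'
#' @param pairs a [PairSet-class].
#' @param path file path.
#' @return `writePairsCSV()`: the path, invisibly; `readPairsCSV()`: a
#'   [PairSet-class].
#' @export
writePairsCSV <- function(pairs, path) {
  p <- pairData(pairs)
  out <- data.frame(
    subject_id = p$subject_id, session_id = p$session_id,
    time_min = p$time_min, bg_mgdl = p$bg, roc_mgdl_min = p$roc,
    dt_min = p$dt, valid_interval = p$valid_interval,
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writePairsCSV
#' @export
readPairsCSV <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .requireColumns(df, c(
    "subject_id", "session_id", "time_min", "bg_mgdl",
    "roc_mgdl_min", "dt_min", "valid_interval"
  ), path)
  PairSet(data.frame(
    subject_id = as.character(df$subject_id),
    session_id = as.character(df$session_id),
    time_min = df$time_min, bg = df$bg_mgdl, roc = df$roc_mgdl_min,
    dt = df$dt_min, valid_interval = as.logical(df$valid_interval),
    index = seq_len(nrow(df)), stringsAsFactors = FALSE
  ))
}
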