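## Unit handling. The molar mass convention 1 mmol/L = 18.016 mg/dL is used
## because it reproduces every customary printed pair after display rounding
## (70 -> 3.9, 300 -> 16.7, 185 -> 10.3, 115 -> 6.4, ...). Internal values
## are never rounded; rounding is display-only.

#' @name glucoseUnits
#' @title Glucose and RoC unit conversion
#'
#' @description Exact conversion between mg/dL and mmol/L (factor
#' 18.016 mg/dL per mmol/L) for glucose concentrations and between
#' mg/(dL*min) and mmol/(L*min) for rates of change, plus display helpers
#' applying the customary rounding: mmol/L to 1 decimal, mg/dL to integer,
#' RoC in mmol/(L*min) to 2 decimals.
#'
#' @param x numeric vector of values.
#' @param from,to unit names; for glucose one of `"mg/dL"`, `"mmol/L"`,
#'   for RoC one of `"mg/dL/min"`, `"mmol/L/min"`.
#' @param unit target display unit.
#' @return `convertUnit()` and `convertRoC()` return the exactly converted
#'   numeric vector; `displayGlucose()` and `displayRoC()` return the
#'   rounded display value.
#' @examples
#' displayGlucose(70, "mmol/L")   # 3.9
#' displayGlucose(185, "mmol/L")  # 10.3
#' displayRoC(1.5, "mmol/L/min")  # 0.08
NULL

#' @rdname glucoseUnits
#' @export
MGDL_PER_MMOLL <- 18.016

.normGlucoseUnit <- function(unit) {
  u <- tolower(gsub("[[:space:]]", "", unit))
  out <- character(length(u))
  out[u %in% c("mg/dl", "mgdl", "mg_dl")] <- "mg/dL"
  out[u %in% c("mmol/l", "mmoll", "mmol_l")] <- "mmol/L"
  if (any(out == "")) {
    stop("unknown glucose unit: ", paste(unique(unit[out == ""]), collapse = ", "))
  }
  out
}

.normRocUnit <- function(unit) {
  u <- tolower(gsub("[[:space:]()·*]", "", unit))
  out <- character(length(u))
  out[u %in% c("mg/dl/min", "mgdlmin", "mg/dlmin")] <- "mg/dL/min"
  out[u %in% c("mmol/l/min", "mmollmin", "mmol/lmin")] <- "mmol/L/min"
  if (any(out == "")) {
    stop("unknown RoC unit: ", paste(unique(unit[out == ""]), collapse = ", "))
  }
  out
}

#' @rdname glucoseUnits
#' @export
convertUnit <- function(x, from, to) {
  stopifnot(is.numeric(x))
  from <- rep_len(.normGlucoseUnit(from), length(x))
  to <- rep_len(.normGlucoseUnit(to), length(x))
  out <- x
  out[from == "mg/dL" & to == "mmol/L"] <-
    x[from == "mg/dL" & to == "mmol/L"] / MGDL_PER_MMOLL
  out[from == "mmol/L" & to == "mg/dL"] <-
    x[from == "mmol/L" & to == "mg/dL"] * MGDL_PER_MMOLL
  out
}

#' @rdname glucoseUnits
#' @export
convertRoC <- function(x, from, to) {
  stopifnot(is.numeric(x), all(is.finite(x)))
  from <- rep_len(.normRocUnit(from), length(x))
  to <- rep_len(.normRocUnit(to), length(x))
  out <- x
  out[from == "mg/dL/min" & to == "mmol/L/min"] <-
    x[from == "mg/dL/min" & to == "mmol/L/min"] / MGDL_PER_MMOLL
  out[from == "mmol/L/min" & to == "mg/dL/min"] <-
    x[from == "mmol/L/min" & to == "mg/dL/min"] * MGDL_PER_MMOLL
  out
}

## round half away from zero (commercial rounding), used for display only:
## base round() rounds half to even, which is wrong for e.g. 16.65 -> 16.7
.roundHalfUp <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' @rdname glucoseUnits
#' @export
displayGlucose <- function(x, unit = "mg/dL") {
  unit <- .normGlucoseUnit(unit)
  if (unit == "mg/dL") {
    .roundHalfUp(x, 0)
  } else {
    .roundHalfUp(x / MGDL_PER_MMOLL, 1)
  }
}

#' @rdname glucoseUnits
#' @export
displayRoC <- function(x, unit = "mg/dL/min") {
  unit <- .normRocUnit(unit)
  if (unit == "mg/dL/min") {
    .roundHalfUp(x, 2)
  } else {
    .roundHalfUp(x / MGDL_PER_MMOLL, 2)
  }
}

#' Duplicate capillary measurements: retest rule and resolution
#'
#' @description During free-living testing, capillary measurements are
#' performed in duplicate from the same finger prick. A third (retest)
#' measurement is indicated when the duplicate disagrees with the first
#' measurement by more than +/-10% (first measurement >= 100 mg/dL) or by
#' more than +/-10 mg/dL (first measurement < 100 mg/dL); both comparisons
#' are strict ("exceeds").
#'
#' `resolveDuplicate()` combines the measurements into a single comparator
#' value: the mean of the duplicate, or the median of all three when a
#' retest was performed (robust to one handling error).
#'
#' @param first,second,third numeric vectors of glucose values in mg/dL;
#'   `third` may be `NA` where no retest was performed.
#' @return `retestRequired()`: logical vector; `resolveDuplicate()`:
#'   numeric vector of resolved values in mg/dL.
#' @examples
#' retestRequired(100, 110)  # FALSE: exactly 10% does not exceed 10%
#' retestRequired(100, 111)  # TRUE
#' retestRequired(80, 91)    # TRUE: 11 mg/dL > 10 mg/dL (low branch)
#' resolveDuplicate(100, 110)       # 105
#' resolveDuplicate(100, 111, 102)  # 102 (median of three)
#' @export
retestRequired <- function(first, second) {
  stopifnot(is.numeric(first), is.numeric(second))
  stopifnot(all(is.finite(first)), all(is.finite(second)), all(first > 0))
  ifelse(first >= 100,
    abs(second - first) / first > 0.10,
    abs(second - first) > 10
  )
}

#' @rdname retestRequired
#' @export
resolveDuplicate <- function(first, second, third = NA_real_) {
  stopifnot(is.numeric(first), is.numeric(second))
  third <- rep_len(as.numeric(third), length(first))
  out <- (first + second) / 2
  has3 <- !is.na(third)
  if (any(has3)) {
    out[has3] <- mapply(
      function(a, b, c) stats::median(c(a, b, c)),
      first[has3], second[has3], third[has3]
    )
  }
  out
}

## evaluate expr under a fixed RNG state without disturbing the caller's
.withSeed <- function(seed, expr) {
  if (is.null(seed)) {
    return(eval.parent(substitute(expr)))
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}
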