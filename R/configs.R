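## Configuration objects. Defaults are the proposed values of the comparator
## data characterization framework; all glucose constants in mg/dL, RoC in
## mg/(dL*min), times in minutes.

#' RegionConfig: geometry of the dynamic glucose region plot
#'
#' Boundary constants of the five DGR regions. The alert regions use a
#' 30-minute linear projection at the current RoC: a pair is in `ALERT_LOW`
#' when BG >= 70 mg/dL, RoC < -1 mg/(dL*min) and the projection
#' `bg + 30 * roc` falls below 70 mg/dL; `ALERT_HIGH` mirrors this with
#' RoC > +1.5 mg/(dL*min), BG <= 300 mg/dL and projection above 250 mg/dL.
#'
#' @slot bgLow numeric(1), BG threshold of the `BG_LOW` region (70 mg/dL).
#' @slot bgHigh numeric(1), BG threshold of the `BG_HIGH` region (300 mg/dL).
#' @slot hypoTarget numeric(1), projection target of `ALERT_LOW` (70 mg/dL).
#' @slot hyperTarget numeric(1), projection target of `ALERT_HIGH`
#'   (250 mg/dL, the level 2 hyperglycemia threshold).
#' @slot horizon numeric(1), projection horizon in minutes (30).
#' @slot alertLowRoC numeric(1), RoC threshold of `ALERT_LOW`
#'   (-1 mg/(dL*min)).
#' @slot alertHighRoC numeric(1), RoC threshold of `ALERT_HIGH`
#'   (+1.5 mg/(dL*min)).
#' @export
setClass("RegionConfig",
  representation(
    bgLow = "numeric",
    bgHigh = "numeric",
    hypoTarget = "numeric",
    hyperTarget = "numeric",
    horizon = "numeric",
    alertLowRoC = "numeric",
    alertHighRoC = "numeric"
  ),
  prototype(
    bgLow = 70, bgHigh = 300, hypoTarget = 70, hyperTarget = 250,
    horizon = 30, alertLowRoC = -1, alertHighRoC = 1.5
  )
)

setValidity("RegionConfig", function(object) {
  v <- c(
    object@bgLow, object@bgHigh, object@hypoTarget, object@hyperTarget,
    object@horizon, object@alertLowRoC, object@alertHighRoC
  )
  if (length(v) != 7L || any(!is.finite(v))) {
    return("all fields must be single finite numbers")
  }
  if (!(object@bgLow < object@hyperTarget && object@hyperTarget < object@bgHigh)) {
    return("thresholds must be ordered: bgLow < hyperTarget < bgHigh")
  }
  if (object@horizon <= 0) return("horizon must be positive")
  if (object@alertLowRoC >= 0) return("alertLowRoC must be negative")
  if (object@alertHighRoC <= 0) return("alertHighRoC must be positive")
  TRUE
})

#' @rdname RegionConfig-class
#' @param bgLow,bgHigh,hypoTarget,hyperTarget,horizon,alertLowRoC,alertHighRoC
#'   see the corresponding slots.
#' @return A `RegionConfig` object.
#' @examples
#' RegionConfig()
#' @export
RegionConfig <- function(bgLow = 70, bgHigh = 300, hypoTarget = 70,
                         hyperTarget = 250, horizon = 30,
                         alertLowRoC = -1, alertHighRoC = 1.5) {
  methods::new("RegionConfig",
    bgLow = bgLow, bgHigh = bgHigh, hypoTarget = hypoTarget,
    hyperTarget = hyperTarget, horizon = horizon,
    alertLowRoC = alertLowRoC, alertHighRoC = alertHighRoC
  )
}

#' DistributionRequirements: recommended comparator data distribution
#'
#' At least `minCriticalFraction` of RoC-BG pairs in each of the four
#' critical regions and at most `maxNeutralFraction` in the neutral region.
#' The defaults (0.075 and 0.70) are mutually consistent:
#' 4 x 0.075 + 0.70 = 1. Compliance comparisons are performed with exact
#' integer arithmetic; fractions are interpreted at a resolution of 1e-4
#' (i.e. specified to at most four decimal places).
#'
#' @slot minCriticalFraction numeric(1), minimum fraction per critical
#'   region (default 0.075).
#' @slot maxNeutralFraction numeric(1), maximum neutral fraction
#'   (default 0.70).
#' @export
setClass("DistributionRequirements",
  representation(
    minCriticalFraction = "numeric",
    maxNeutralFraction = "numeric"
  ),
  prototype(minCriticalFraction = 0.075, maxNeutralFraction = 0.70)
)

setValidity("DistributionRequirements", function(object) {
  f <- object@minCriticalFraction
  g <- object@maxNeutralFraction
  if (length(f) != 1L || length(g) != 1L || !is.finite(f) || !is.finite(g)) {
    return("fractions must be single finite numbers")
  }
  if (f < 0 || f > 0.25 || g < 0 || g > 1) {
    return("fractions out of range")
  }
  if (4 * f + g > 1 + 1e-12) {
    return("inconsistent requirements: 4 * minCriticalFraction + maxNeutralFraction must be <= 1")
  }
  TRUE
})

#' @rdname DistributionRequirements-class
#' @param minCriticalFraction,maxNeutralFraction see the corresponding slots.
#' @return A `DistributionRequirements` object.
#' @export
DistributionRequirements <- function(minCriticalFraction = 0.075,
                                     maxNeutralFraction = 0.70) {
  methods::new("DistributionRequirements",
    minCriticalFraction = minCriticalFraction,
    maxNeutralFraction = maxNeutralFraction
  )
}

## exact rational form of a fraction given to <= 4 decimals
.fracNumDen <- function(f) {
  num <- round(f * 10000)
  if (abs(num - f * 10000) > 1e-9) {
    stop("requirement fractions must be specified to at most 4 decimal places")
  }
  c(num = num, den = 10000)
}

#' EliminationConfig: elliptical distance measure for neutral elimination
#'
#' The distance of an RoC-BG pair from the center of the neutral region is
#' `D = sqrt((roc / a)^2 + ((bg - bgCenter) / b)^2)`. With the default
#' constants the locus D = 1 is an ellipse through (roc = 0, bg = 70),
#' (roc = 0, bg = 300) and (roc = +/-1, bg = 185): it spans the neutral
#' region's horizontal edges, where excluding pairs with D > 1 would reach
#' into the BG low/high regions and flags the data set as possibly
#' inadequate.
#'
#' @slot a numeric(1), RoC semi-axis in mg/(dL*min) (default 1).
#' @slot b numeric(1), BG semi-axis in mg/dL (default 115).
#' @slot bgCenter numeric(1), BG center of the neutral region in mg/dL
#'   (default 185).
#' @slot dAdequacyLimit numeric(1), adequacy limit on excluded D (default 1).
#' @export
setClass("EliminationConfig",
  representation(
    a = "numeric",
    b = "numeric",
    bgCenter = "numeric",
    dAdequacyLimit = "numeric"
  ),
  prototype(a = 1, b = 115, bgCenter = 185, dAdequacyLimit = 1)
)

setValidity("EliminationConfig", function(object) {
  v <- c(object@a, object@b, object@bgCenter, object@dAdequacyLimit)
  if (length(v) != 4L || any(!is.finite(v))) {
    return("all fields must be single finite numbers")
  }
  if (object@a <= 0 || object@b <= 0) return("a and b must be positive")
  if (object@bgCenter <= 0) return("bgCenter must be positive")
  TRUE
})

#' @rdname EliminationConfig-class
#' @param a,b,bgCenter,dAdequacyLimit see the corresponding slots.
#' @return An `EliminationConfig` object.
#' @examples
#' distanceD(bg = 70, roc = 0, cfg = EliminationConfig())  # 1
#' @export
EliminationConfig <- function(a = 1, b = 115, bgCenter = 185,
                              dAdequacyLimit = 1) {
  methods::new("EliminationConfig",
    a = a, b = b, bgCenter = bgCenter, dAdequacyLimit = dAdequacyLimit
  )
}

#' EpisodeConfig: hypo-/hyperglycemic episode definitions
#'
#' An episode is a maximal run of consecutive CGM readings strictly below
#' `hypoThreshold` (hypo) or strictly above `hyperThreshold` (hyper).
#' Episodes spanning less than `minDuration` or more than `maxDuration`
#' minutes are excluded from the analysis set. Qualification requires a
#' complete, gap-free `lookback` window before the episode in which glucose
#' stays on the in-range side of the threshold and changes monotonically
#' toward it (RoC <= 0 before hypo, RoC >= 0 before hyper).
#'
#' @slot hypoThreshold numeric(1), mg/dL (default 70).
#' @slot hyperThreshold numeric(1), mg/dL (default 250).
#' @slot minDuration numeric(1), minutes (default 15).
#' @slot maxDuration numeric(1), minutes (default 120).
#' @slot lookback numeric(1), minutes (default 60).
#' @slot durationConvention character(1), `"span"` (default; duration is
#'   `(run length - 1) * interval`, the time spanned between the first and
#'   last beyond-threshold sample) or `"count"` (`run length * interval`).
#' @export
setClass("EpisodeConfig",
  representation(
    hypoThreshold = "numeric",
    hyperThreshold = "numeric",
    minDuration = "numeric",
    maxDuration = "numeric",
    lookback = "numeric",
    durationConvention = "character"
  ),
  prototype(
    hypoThreshold = 70, hyperThreshold = 250, minDuration = 15,
    maxDuration = 120, lookback = 60, durationConvention = "span"
  )
)

setValidity("EpisodeConfig", function(object) {
  if (!(object@minDuration > 0 && object@minDuration <= object@maxDuration)) {
    return("need 0 < minDuration <= maxDuration")
  }
  if (object@lookback <= 0) return("lookback must be positive")
  if (!object@durationConvention %in% c("span", "count")) {
    return("durationConvention must be 'span' or 'count'")
  }
  TRUE
})

#' @rdname EpisodeConfig-class
#' @param hypoThreshold,hyperThreshold,minDuration,maxDuration,lookback,durationConvention
#'   see the corresponding slots.
#' @return An `EpisodeConfig` object.
#' @export
EpisodeConfig <- function(hypoThreshold = 70, hyperThreshold = 250,
                          minDuration = 15, maxDuration = 120,
                          lookback = 60, durationConvention = "span") {
  methods::new("EpisodeConfig",
    hypoThreshold = hypoThreshold, hyperThreshold = hyperThreshold,
    minDuration = minDuration, maxDuration = maxDuration,
    lookback = lookback, durationConvention = durationConvention
  )
}

#' SessionParams: in-clinic session generator parameters
#'
#' Parameters of the synthetic target glucose profile (TGP) session: start
#' in range, post-meal rise, sustained plateau above 300 mg/dL for about 30
#' minutes, rapid fall into a sustained plateau below 70 mg/dL for about 30
#' minutes, then recovery to 100-180 mg/dL over a 7-hour frequent sampling
#' period sampled every 15 minutes. A fraction `1 - manipulationFraction`
#' of sessions instead follow a routine-therapy shape (moderate post-meal
#' excursion, no induced hypoglycemia).
#'
#' @slot fspDuration numeric(1), minutes (default 420).
#' @slot samplingInterval numeric(1), minutes (default 15).
#' @slot startRange numeric(2), mg/dL range of the starting level
#'   (default c(100, 160), within the 70-180 mg/dL target range).
#' @slot highPlateau numeric(1), minutes sustained above 300 (default 30).
#' @slot hypoPlateau numeric(1), minutes sustained below 70 (default 30).
#' @slot recoveryRange numeric(2), mg/dL range of the final stable level
#'   (default c(110, 170), within 100-180).
#' @slot timingJitterSd numeric(1), sd of anchor-time jitter in minutes
#'   (default 20).
#' @slot levelJitterSd numeric(1), sd of anchor-level jitter in mg/dL
#'   (default 15).
#' @slot manipulationFraction numeric(1), fraction of sessions undergoing
#'   the full glucose manipulation (default 0.78).
#' @slot measurementCv numeric(1), multiplicative comparator measurement CV
#'   (default 0.02).
#' @export
setClass("SessionParams",
  representation(
    fspDuration = "numeric",
    samplingInterval = "numeric",
    startRange = "numeric",
    highPlateau = "numeric",
    hypoPlateau = "numeric",
    recoveryRange = "numeric",
    timingJitterSd = "numeric",
    levelJitterSd = "numeric",
    manipulationFraction = "numeric",
    measurementCv = "numeric"
  ),
  prototype(
    fspDuration = 420, samplingInterval = 15, startRange = c(100, 160),
    highPlateau = 30, hypoPlateau = 30, recoveryRange = c(110, 170),
    timingJitterSd = 20, levelJitterSd = 15,
    manipulationFraction = 0.78, measurementCv = 0.02
  )
)

setValidity("SessionParams", function(object) {
  if (object@fspDuration %% object@samplingInterval != 0) {
    return("fspDuration must be divisible by samplingInterval")
  }
  if (length(object@startRange) != 2L || diff(object@startRange) < 0) {
    return("startRange must be an ordered length-2 range")
  }
  if (length(object@recoveryRange) != 2L || diff(object@recoveryRange) < 0) {
    return("recoveryRange must be an ordered length-2 range")
  }
  if (object@manipulationFraction < 0 || object@manipulationFraction > 1) {
    return("manipulationFraction must be in [0, 1]")
  }
  if (object@measurementCv < 0 || object@measurementCv > 0.5) {
    return("measurementCv must be in [0, 0.5]")
  }
  TRUE
})

#' @rdname SessionParams-class
#' @param fspDuration,samplingInterval,startRange,highPlateau,hypoPlateau,recoveryRange,timingJitterSd,levelJitterSd,manipulationFraction,measurementCv
#'   see the corresponding slots.
#' @return A `SessionParams` object.
#' @export
SessionParams <- function(fspDuration = 420, samplingInterval = 15,
                          startRange = c(100, 160), highPlateau = 30,
                          hypoPlateau = 30, recoveryRange = c(110, 170),
                          timingJitterSd = 20, levelJitterSd = 15,
                          manipulationFraction = 0.78, measurementCv = 0.02) {
  methods::new("SessionParams",
    fspDuration = fspDuration, samplingInterval = samplingInterval,
    startRange = startRange, highPlateau = highPlateau,
    hypoPlateau = hypoPlateau, recoveryRange = recoveryRange,
    timingJitterSd = timingJitterSd, levelJitterSd = levelJitterSd,
    manipulationFraction = manipulationFraction, measurementCv = measurementCv
  )
}

#' CohortParams: study cohort and scheduling parameters
#'
#' @slot nParticipants integer(1).
#' @slot t1dFraction numeric(1), fraction with type 1 diabetes
#'   (default 0.75, the recommended minimum).
#' @slot sensorLifetimeDays numeric(1), default 14.
#' @slot sessionsPerParticipant integer(1), default 3.
#' @export
setClass("CohortParams",
  representation(
    nParticipants = "integer",
    t1dFraction = "numeric",
    sensorLifetimeDays = "numeric",
    sessionsPerParticipant = "integer"
  ),
  prototype(
    nParticipants = 50L, t1dFraction = 0.75,
    sensorLifetimeDays = 14, sessionsPerParticipant = 3L
  )
)

setValidity("CohortParams", function(object) {
  if (object@nParticipants < 1L) return("nParticipants must be >= 1")
  if (object@t1dFraction < 0 || object@t1dFraction > 1) {
    return("t1dFraction must be in [0, 1]")
  }
  TRUE
})

#' @rdname CohortParams-class
#' @param nParticipants,t1dFraction,sensorLifetimeDays,sessionsPerParticipant
#'   see the corresponding slots.
#' @return A `CohortParams` object.
#' @export
CohortParams <- function(nParticipants = 50, t1dFraction = 0.75,
                         sensorLifetimeDays = 14,
                         sessionsPerParticipant = 3) {
  methods::new("CohortParams",
    nParticipants = as.integer(nParticipants),
    t1dFraction = t1dFraction,
    sensorLifetimeDays = sensorLifetimeDays,
    sessionsPerParticipant = as.integer(sessionsPerParticipant)
  )
}
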