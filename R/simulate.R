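## Synthetic-data generation emulating the proposed testing procedures:
## in-clinic target glucose profile (TGP) sessions sampled on a 15-min
## frequent-sampling grid, free-living seven-point capillary days with
## duplicate measurements, and session scheduling across the sensor
## lifetime. The generator is shape-based (anchor points + monotone
## interpolation + multiplicative noise), not a physiological
## insulin-carbohydrate model.

.truncnorm1 <- function(mean, sd, lo, hi) {
  min(hi, max(lo, stats::rnorm(1L, mean, sd)))
}

## jitter anchor times, keep strict ordering with a minimum gap
.jitterTimes <- function(t, sd, tmax, minGap = 12) {
  if (sd > 0) {
    inner <- seq_along(t)[-c(1L, length(t))]
    t[inner] <- t[inner] + pmin(2 * sd, pmax(-2 * sd, stats::rnorm(length(inner), 0, sd)))
  }
  for (i in seq_along(t)[-1L]) t[i] <- max(t[i], t[i - 1L] + minGap)
  t[length(t)] <- tmax
  for (i in rev(seq_along(t)[-length(t)])) t[i] <- min(t[i], t[i + 1L] - minGap)
  t
}

## anchors for a full-manipulation TGP session; assumes an active RNG.
## Designed so that the profile puts roughly 11% of the 28 RoC-BG pairs in
## each critical region (~57% neutral), matching the design target of the
## TGP: a post-meal rise with RoC ~ +2 traversing ALERT_HIGH, a ~30 min
## plateau above 300 (BG_HIGH), a concave fall — steep at first, then
## easing to RoC ~ -1.8 — whose 30-min projection stays below 70 for about
## 45 min so that ALERT_LOW is traversed for ~3 samples, a ~30 min plateau
## below 70 (BG_LOW), then recovery to 100-180 mg/dL. Plateau durations
## are jittered only mildly (sd 5 min) to keep the "sustained ~30 min"
## episodes; the overall timing of the excursion carries the full
## session-to-session timing jitter.
.tgpAnchors <- function(p) {
  S <- .truncnorm1(mean(p@startRange), p@levelJitterSd,
                   p@startRange[1L], p@startRange[2L])
  H <- .truncnorm1(315, p@levelJitterSd, 303, 350)
  L <- .truncnorm1(58, p@levelJitterSd / 2, 45, 66)
  R <- .truncnorm1(mean(p@recoveryRange), p@levelJitterSd,
                   p@recoveryRange[1L], p@recoveryRange[2L])
  tmax <- p@fspDuration

  plateauSd <- min(5, p@timingJitterSd / 4) # mild: keep "sustained ~30 min"
  tPeak <- .truncnorm1(105, p@timingJitterSd, 75, 140)
  highDur <- .truncnorm1(p@highPlateau, plateauSd, 0.7 * p@highPlateau, 1.5 * p@highPlateau)
  d1 <- .truncnorm1(20, p@timingJitterSd / 4, 12, 30) # steep upper fall
  d2 <- .truncnorm1(25, p@timingJitterSd / 4, 15, 35) # mid fall
  d3 <- .truncnorm1(35, p@timingJitterSd / 4, 25, 45) # easing lower fall
  hypoDur <- .truncnorm1(p@hypoPlateau, plateauSd, 0.7 * p@hypoPlateau, 1.5 * p@hypoPlateau)

  tHigh2 <- tPeak + highDur
  tHypo1 <- tHigh2 + d1 + d2 + d3
  tHypo2 <- tHypo1 + hypoDur
  time <- c(
    0, tPeak * (35 / 105), tPeak * (80 / 105), tPeak, tHigh2,
    tHigh2 + d1, tHigh2 + d1 + d2, tHypo1, tHypo2,
    tHypo2 + 25, tHypo2 + 75, tmax
  )
  level <- c(S, S + 55, 275, H, H, 210, 120, L, L, 95, R, R)
  if (p@levelJitterSd > 0) {
    jit <- c(2L, 3L, 6L, 7L, 10L, 11L)
    level[jit] <- level[jit] + stats::rnorm(length(jit), 0, p@levelJitterSd)
    level[12L] <- level[11L]
  }
  ## keep the designed shape monotone between the plateaus
  level[2L] <- min(max(level[2L], S + 20), 262)
  level[3L] <- min(max(level[3L], level[2L] + 8), H - 8)
  level[6L] <- min(max(level[6L], L + 90), H - 30)
  level[7L] <- min(max(level[7L], L + 45), level[6L] - 30)
  level[10L] <- min(max(level[10L], L + 15), 140)
  level[11L] <- min(max(level[11L], p@recoveryRange[1L]), p@recoveryRange[2L])
  level[12L] <- level[11L]
  time <- .jitterTimes(time, 0, tmax) # enforce ordering/min gaps only
  list(time = time, level = level, type = "manipulated")
}

## routine-therapy session: moderate post-meal excursion, no induced
## hypoglycemia, freely chosen second meal late in the session
.routineAnchors <- function(p) {
  S <- .truncnorm1(mean(p@startRange), p@levelJitterSd,
                   p@startRange[1L], p@startRange[2L])
  P <- .truncnorm1(225, p@levelJitterSd, 200, 250)
  R <- .truncnorm1(mean(p@recoveryRange), p@levelJitterSd,
                   p@recoveryRange[1L], p@recoveryRange[2L])
  tmax <- p@fspDuration
  time <- c(0, 45, 90, 150, 240, 330, 370, tmax)
  level <- c(S, (S + P) / 2, P, 190, 135, 150, 205, R)
  time <- .jitterTimes(time, p@timingJitterSd, tmax)
  if (p@levelJitterSd > 0) {
    jit <- c(4L, 5L, 6L, 7L)
    level[jit] <- level[jit] + stats::rnorm(length(jit), 0, p@levelJitterSd)
  }
  level[4L] <- min(max(level[4L], 150), P - 5)
  level[5L] <- min(max(level[5L], 100), level[4L] - 5)
  level[6L] <- min(max(level[6L], level[5L]), 200)
  level[7L] <- min(max(level[7L], level[6L] + 5), 260)
  list(time = time, level = level, type = "routine")
}

.sessionProfile <- function(p) {
  manipulated <- stats::runif(1L) < p@manipulationFraction
  a <- if (manipulated) .tgpAnchors(p) else .routineAnchors(p)
  fn <- stats::splinefun(a$time, a$level, method = "monoH.FC")
  list(fn = fn, type = a$type)
}

#' Generate a synthetic in-clinic comparator session
#'
#' Draws one frequent-sampling-period session following the target glucose
#' profile: start in range, post-meal rise traversing the high-alert
#' region, ~30 min sustained above 300 mg/dL, rapid fall traversing the
#' low-alert region, ~30 min sustained below 70 mg/dL, and recovery to
#' 100-180 mg/dL, sampled every 15 min over 7 h (29 samples, hence 28
#' RoC-BG pairs). With probability `1 - manipulationFraction` the session
#' instead follows a routine-therapy shape (moderate excursion, no induced
#' hypoglycemia). Anchor times and levels are jittered per session and
#' multiplicative measurement noise at the configured CV is applied; all
#' values are clamped to [40, 400] mg/dL.
#'
#' @param params a [SessionParams-class].
#' @param seed optional integer seed (RNG state is restored afterwards);
#'   omit when calling inside an externally seeded stream.
#' @param subjectId,sessionId identifiers for the generated series.
#' @return A [ComparatorSeries-class]; the profile type
#'   (`"manipulated"`/`"routine"`) is available as
#'   `attr(x, "profileType")`.
#' @examples
#' s <- generateSession(SessionParams(manipulationFraction = 1), seed = 1)
#' length(s@glucose)  # 29
#' @export
generateSession <- function(params = SessionParams(), seed = NULL,
                            subjectId = "SIM", sessionId = "S1") {
  .withSeed(seed, {
    prof <- .sessionProfile(params)
    grid <- seq(0, params@fspDuration, by = params@samplingInterval)
    latent <- prof$fn(grid)
    noisy <- latent * (1 + stats::rnorm(length(grid), 0, params@measurementCv))
    noisy <- pmin(400, pmax(40, noisy))
    out <- ComparatorSeries(subjectId, sessionId,
      time = grid, glucose = noisy,
      nominalInterval = params@samplingInterval
    )
    attr(out, "profileType") <- prof$type
    out
  })
}

#' Generate a free-living seven-point capillary day
#'
#' Seven scheduled capillary measurement points (immediately before and 2 h
#' after breakfast, lunch and dinner, and before bed) with timing jitter.
#' Each point is measured in duplicate around a latent true value with the
#' given per-measurement CV; a third (retest) measurement is generated
#' exactly when [retestRequired()] fires on the simulated duplicate, and
#' the resolved comparator value is computed with [resolveDuplicate()].
#'
#' @param seed optional integer seed.
#' @param cv per-measurement coefficient of variation of the capillary
#'   meter (default 0.05).
#' @param timingJitterSd sd of measurement-time jitter in minutes
#'   (default 15).
#' @return A data.frame with one row per measurement point: `slot`,
#'   `time_min` (minutes from midnight), `latent`, `first`, `second`,
#'   `third` (NA when no retest), `retest`, `resolved`.
#' @examples
#' day <- generateFreeLivingDay(seed = 1)
#' nrow(day)  # 7
#' @export
generateFreeLivingDay <- function(seed = NULL, cv = 0.05, timingJitterSd = 15) {
  .withSeed(seed, {
    slots <- c(
      "pre_breakfast", "post_breakfast", "pre_lunch", "post_lunch",
      "pre_dinner", "post_dinner", "bedtime"
    )
    base <- c(420, 540, 750, 870, 1110, 1230, 1380)
    isPost <- grepl("^post", slots)
    t <- base + pmin(2 * timingJitterSd, pmax(
      -2 * timingJitterSd,
      stats::rnorm(length(base), 0, timingJitterSd)
    ))
    latent <- numeric(length(slots))
    latent[!isPost] <- pmin(180, pmax(70, stats::rnorm(sum(!isPost), 120, 20)))
    latent[isPost] <- pmin(280, pmax(90, stats::rnorm(sum(isPost), 165, 30)))
    first <- pmax(20, latent * (1 + stats::rnorm(length(latent), 0, cv)))
    second <- pmax(20, latent * (1 + stats::rnorm(length(latent), 0, cv)))
    retest <- retestRequired(first, second)
    third <- rep(NA_real_, length(latent))
    if (any(retest)) {
      third[retest] <- pmax(
        20,
        latent[retest] * (1 + stats::rnorm(sum(retest), 0, cv))
      )
    }
    data.frame(
      slot = slots, time_min = t, latent = latent,
      first = first, second = second, third = third,
      retest = retest, resolved = resolveDuplicate(first, second, third),
      stringsAsFactors = FALSE
    )
  })
}

#' Schedule in-clinic sessions across the sensor lifetime
#'
#' For the 14-day sensor design with three sessions per participant, each
#' participant is assigned one session day from each of the beginning
#' ({1, 2, 3}), middle ({7, 8, 9}) and end ({13, 14, 15}) of the sensor
#' lifetime, such that across the cohort the nine candidate days are used
#' as evenly as possible (max count - min count <= 1). Diabetes type is
#' assigned so that at least `t1dFraction` of participants have type 1
#' diabetes.
#'
#' @param cohort a [CohortParams-class]; only the 14-day, three-session
#'   design is supported.
#' @param seed optional integer seed.
#' @return A data.frame with columns `participant_id`, `diabetes_type`
#'   (`"T1D"`/`"T2D"`), `block` (`beginning`/`middle`/`end`), `day`.
#' @examples
#' sched <- scheduleSessions(CohortParams(nParticipants = 9), seed = 1)
#' table(sched$day)  # each of the nine days used exactly 3 times
#' @export
scheduleSessions <- function(cohort = CohortParams(), seed = NULL) {
  if (cohort@sensorLifetimeDays != 14 || cohort@sessionsPerParticipant != 3L) {
    stop("session scheduling is defined for the 14-day, three-session design")
  }
  .withSeed(seed, {
    n <- cohort@nParticipants
    ids <- sprintf("P%03d", seq_len(n))
    blocks <- list(
      beginning = c(1, 2, 3), middle = c(7, 8, 9), end = c(13, 14, 15)
    )
    out <- lapply(names(blocks), function(b) {
      days <- blocks[[b]][((sample.int(n) - 1L) %% 3L) + 1L]
      data.frame(
        participant_id = ids, block = b, day = days,
        stringsAsFactors = FALSE
      )
    })
    out <- do.call(rbind, out)
    nT1d <- ceiling(cohort@t1dFraction * n)
    t1d <- ids %in% sample(ids, nT1d)
    out$diabetes_type <- ifelse(t1d[match(out$participant_id, ids)], "T1D", "T2D")
    out <- out[order(out$participant_id, out$day), c(
      "participant_id", "diabetes_type", "block", "day"
    )]
    rownames(out) <- NULL
    out
  })
}

#' Simulate a full study cohort
#'
#' Draws the session schedule, then one comparator session per scheduled
#' in-clinic day (15-min grid) together with the latent 5-min CGM-style
#' trace of the same profile, from a single seeded RNG stream.
#'
#' @param cohort a [CohortParams-class].
#' @param params a [SessionParams-class].
#' @param seed integer seed; identical seeds give identical cohorts.
#' @return A list with elements `schedule` (data.frame), `comparator`
#'   (named list of [ComparatorSeries-class]), `cgm` (named list of
#'   [CGMTrace-class]) and `manifest` (list of generation settings).
#' @export
simulateCohort <- function(cohort = CohortParams(), params = SessionParams(),
                           seed = 1) {
  .withSeed(seed, {
    schedule <- scheduleSessions(cohort)
    comparator <- list()
    cgm <- list()
    for (i in seq_len(nrow(schedule))) {
      sid <- schedule$participant_id[i]
      sess <- sprintf("D%02d", schedule$day[i])
      prof <- .sessionProfile(params)
      grid <- seq(0, params@fspDuration, by = params@samplingInterval)
      latent <- prof$fn(grid)
      noisy <- pmin(400, pmax(40, latent * (1 + stats::rnorm(length(grid), 0, params@measurementCv))))
      key <- paste(sid, sess, sep = "/")
      comparator[[key]] <- ComparatorSeries(sid, sess,
        time = grid, glucose = noisy, nominalInterval = params@samplingInterval
      )
      attr(comparator[[key]], "profileType") <- prof$type
      cgmGrid <- seq(0, params@fspDuration, by = 5)
      cgm[[key]] <- CGMTrace(key,
        time = cgmGrid,
        glucose = pmin(400, pmax(40, prof$fn(cgmGrid))), interval = 5
      )
    }
    list(
      schedule = schedule, comparator = comparator, cgm = cgm,
      manifest = list(
        nParticipants = cohort@nParticipants,
        sessionsPerParticipant = cohort@sessionsPerParticipant,
        sensorLifetimeDays = cohort@sensorLifetimeDays,
        manipulationFraction = params@manipulationFraction,
        measurementCv = params@measurementCv,
        seed = seed
      )
    )
  })
}

#' Generate a cohort of synthetic pre-hypoglycemia descent traces
#'
#' Mechanism-test generator for the episode analysis: each 5-min trace
#' carries a 60-min monotone, gap-free descent from the in-range band into
#' a short hypoglycemic episode, followed by recovery. With probability
#' `probSteep` the descent is steep (a slow initial decline followed by a
#' fall at roughly -1.6 to -2 mg/(dL*min), which traverses the low-alert
#' region); otherwise it is shallow (a near-linear decline slower than
#' -1 mg/(dL*min), which never enters the low-alert region). Traces are
#' latent (noise-free) so the construction guarantees the region
#' membership it is meant to test.
#'
#' @param n number of traces.
#' @param probSteep probability of a steep descent (default 0.5).
#' @param seed optional integer seed.
#' @return A list with `traces` (named list of [CGMTrace-class]) and
#'   `steep` (named logical vector of the drawn descent type).
#' @export
generateDescentCohort <- function(n, probSteep = 0.5, seed = NULL) {
  .withSeed(seed, {
    traces <- list()
    steep <- logical(n)
    for (i in seq_len(n)) {
      id <- sprintf("T%04d", i)
      steep[i] <- stats::runif(1L) < probSteep
      if (steep[i]) {
        B1 <- stats::runif(1L, 112, 130) # fast-leg RoC in (-1.97, -1.37)
        B0 <- B1 + stats::runif(1L, 10, 25)
        pre1 <- seq(B0, B1, length.out = 7L) # t = 0..30, slow
        pre2 <- seq(B1, 71, length.out = 7L)[-1L] # t = 35..60 fast
        pre <- c(pre1, pre2)[1:12]
      } else {
        B0 <- stats::runif(1L, 108, 122)
        pre <- seq(B0, 71, length.out = 12L) # roc in (-0.95, -0.55)
      }
      epi <- stats::runif(4L, 58, 67) # 4 samples < 70: 15-min episode
      post <- c(75, 95, 115, 130)
      g <- c(pre, epi, post)
      t <- seq(0, by = 5, length.out = length(g))
      traces[[id]] <- CGMTrace(id, time = t, glucose = g, interval = 5)
    }
    list(traces = traces, steep = stats::setNames(steep, names(traces)))
  })
}
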