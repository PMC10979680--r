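test_that("a generated session follows the 7-h frequent sampling grid", {
  s <- generateSession(SessionParams(manipulationFraction = 1), seed = 4)
  expect_s4_class(s, "ComparatorSeries")
  expect_equal(length(s@glucose), 29)
  expect_equal(s@time, seq(0, 420, 15))
  expect_equal(nPairs(computePairs(s)), 28)
  expect_true(all(s@glucose >= 40 & s@glucose <= 400))
})

test_that("the noise-free target profile traverses all four critical regions", {
  p0 <- SessionParams(
    manipulationFraction = 1, timingJitterSd = 0,
    levelJitterSd = 0, measurementCv = 0
  )
  s <- generateSession(p0, seed = 1)
  regions <- classifyPairs(computePairs(s))$region
  expect_true(all(criticalRegions() %in% regions))
  # sustained excursions: at least two consecutive samples beyond each band
  expect_gte(sum(s@glucose > 300), 2)
  expect_gte(sum(s@glucose < 70), 2)
  # deterministic anchors: repeated draws with jitter disabled agree
  s2 <- generateSession(p0, seed = 99)
  expect_equal(s@glucose, s2@glucose, tolerance = 1e-9)
})

test_that("generation is reproducible under a fixed seed", {
  a <- generateSession(SessionParams(), seed = 12)
  b <- generateSession(SessionParams(), seed = 12)
  expect_identical(a@glucose, b@glucose)
  c1 <- simulateCohort(CohortParams(nParticipants = 4), seed = 3)
  c2 <- simulateCohort(CohortParams(nParticipants = 4), seed = 3)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  writeComparatorCSV(c1$comparator, f1)
  writeComparatorCSV(c2$comparator, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("routine-therapy sessions avoid induced hypoglycemia", {
  p <- SessionParams(manipulationFraction = 0)
  for (i in 1:10) {
    s <- generateSession(p, seed = i)
    expect_identical(attr(s, "profileType"), "routine")
    expect_true(all(s@glucose >= 70))
    expect_true(all(s@glucose <= 300))
  }
})

test_that("free-living days carry seven duplicate points and honest retests", {
  day <- generateFreeLivingDay(seed = 2)
  expect_equal(nrow(day), 7)
  expect_true(all(diff(day$time_min) > 0))
  # a third measurement exists exactly when the retest rule fires
  expect_equal(!is.na(day$third), day$retest)
  expect_equal(day$retest, unname(retestRequired(day$first, day$second)))

  # zero measurement noise: duplicates agree, no retest can fire
  dayClean <- generateFreeLivingDay(seed = 3, cv = 0)
  expect_false(any(dayClean$retest))
  expect_equal(dayClean$first, dayClean$second)
})

test_that("retest frequency under inflated noise matches a direct simulation", {
  withr::local_seed(301)
  days <- lapply(1:300, function(i) generateFreeLivingDay(cv = 0.15))
  rate <- mean(unlist(lapply(days, `[[`, "retest")))

  # independent oracle: simulate the stated latent mix (4 of 7 points are
  # pre-meal/bedtime, 3 post-meal) and duplicate noise model directly
  mc <- local({
    m <- 2e5
    pre <- pmin(180, pmax(70, rnorm(m, 120, 20)))
    post <- pmin(280, pmax(90, rnorm(m, 165, 30)))
    lat <- ifelse(runif(m) < 4 / 7, pre, post)
    f <- pmax(20, lat * (1 + rnorm(m, 0, 0.15)))
    s <- pmax(20, lat * (1 + rnorm(m, 0, 0.15)))
    mean(ifelse(f >= 100, abs(s - f) / f > 0.10, abs(s - f) > 10))
  })
  expect_lt(abs(rate - mc), 0.03)
  expect_gt(rate, 0.3) # inflated noise fires retests often
})

test_that("session scheduling balances the nine candidate days", {
  sched9 <- scheduleSessions(CohortParams(nParticipants = 9), seed = 5)
  expect_equal(nrow(sched9), 27)
  expect_true(all(table(sched9$day) == 3))
  expect_setequal(unique(sched9$day), c(1, 2, 3, 7, 8, 9, 13, 14, 15))

  # each participant draws one day per lifetime tercile
  byP <- split(sched9$day, sched9$participant_id)
  for (d in byP) {
    expect_length(intersect(d, 1:3), 1)
    expect_length(intersect(d, 7:9), 1)
    expect_length(intersect(d, 13:15), 1)
  }

  sched10 <- scheduleSessions(CohortParams(nParticipants = 10), seed = 6)
  counts <- table(sched10$day)
  expect_lte(max(counts) - min(counts), 1)

  sched1 <- scheduleSessions(CohortParams(nParticipants = 1), seed = 7)
  expect_equal(nrow(sched1), 3)

  expect_error(
    scheduleSessions(CohortParams(nParticipants = 5, sensorLifetimeDays = 10)),
    "14-day"
  )

  # at least 75% of participants have type 1 diabetes
  frac <- mean(tapply(sched10$diabetes_type, sched10$participant_id, `[`, 1) == "T1D")
  expect_gte(frac, 0.75)
})

test_that("pooled manipulated sessions cover every critical region", {
  withr::local_seed(404)
  p <- SessionParams(manipulationFraction = 1)
  sessions <- lapply(1:50, function(i) generateSession(p))
  rep <- distributionReport(computePairs(sessions))
  expect_true(isCompliant(rep))
  expect_equal(rep@nTotal, 50 * 28)
})
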