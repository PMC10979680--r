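test_that("elliptical distance D matches its anchor points", {
  expect_equal(distanceD(bg = 70, roc = 0), 1)
  expect_equal(distanceD(bg = 300, roc = 0), 1)
  expect_equal(distanceD(bg = 185, roc = 0), 0)
  expect_equal(distanceD(bg = 185, roc = 1), 1)
  expect_equal(distanceD(bg = 185, roc = -1), 1)
  expect_equal(distanceD(bg = 277, roc = 0.6), 1) # 0.36 + (92/115)^2 = 1
})

test_that("D is invariant under exact unit conversion", {
  withr::local_seed(21)
  bg <- runif(300, 40, 400)
  roc <- runif(300, -5, 5)
  f <- MGDL_PER_MMOLL
  cfgMmol <- EliminationConfig(a = 1 / f, b = 115 / f, bgCenter = 185 / f)
  expect_equal(distanceD(bg, roc), distanceD(bg / f, roc / f, cfgMmol))
})

test_that("minimal exclusion count: closed form agrees with derived cases", {
  withr::local_seed(31)
  rep28 <- distributionReport(makePairSet(list(
    BG_LOW = 2, BG_HIGH = 2, ALERT_LOW = 2, ALERT_HIGH = 2, NEUTRAL = 20
  )))
  expect_equal(minExclusions(rep28), 2) # 2/26 = 7.69% >= 7.5%
  rep40 <- distributionReport(makePairSet(list(
    BG_LOW = 3, BG_HIGH = 3, ALERT_LOW = 3, ALERT_HIGH = 3, NEUTRAL = 28
  )))
  expect_equal(minExclusions(rep40), 0) # inclusive boundary
  expect_equal(minExclusions(distributionReport(makePairSet(list(
    BG_LOW = 1, BG_HIGH = 1, ALERT_LOW = 1, ALERT_HIGH = 1
  )))), 0)
  # a critical region with zero pairs is infeasible
  expect_equal(minExclusions(distributionReport(makePairSet(list(
    BG_LOW = 1, BG_HIGH = 1, ALERT_LOW = 1, NEUTRAL = 20
  )))), Inf)
})

test_that("elimination removes exactly the smallest-D neutral pairs", {
  withr::local_seed(17)
  ps <- makePairSet(list(
    BG_LOW = 2, BG_HIGH = 2, ALERT_LOW = 2, ALERT_HIGH = 2, NEUTRAL = 20
  ))
  res <- eliminatePairs(ps)
  expect_true(res@feasible)
  expect_equal(res@k, 2)
  expect_true(isCompliant(res@after))
  expect_lte(regionFractions(res@after)[["NEUTRAL"]], 0.70)

  # excluded pairs are neutral, sorted ascending by D, and are the k
  # candidates with the smallest D
  tab <- classifyPairs(ps)
  tab$D <- distanceD(tab$bg, tab$roc)
  neutralD <- sort(tab$D[tab$region == "NEUTRAL"])
  expect_equal(res@excluded$D, neutralD[1:2])
  expect_true(all(res@excluded$region == "NEUTRAL"))

  # kept + excluded partition the input, critical pairs all kept
  expect_equal(nPairs(res@kept) + res@k, nPairs(ps))
  keptRegions <- classifyPairs(res@kept)$region
  expect_equal(
    sum(keptRegions %in% criticalRegions()),
    sum(tab$region %in% criticalRegions())
  )

  # already-compliant input is untouched
  res0 <- eliminatePairs(makePairSet(list(
    BG_LOW = 2, BG_HIGH = 2, ALERT_LOW = 2, ALERT_HIGH = 2
  )))
  expect_equal(res0@k, 0)
  expect_equal(nPairs(res0@kept), 8)
})

test_that("infeasible and inadequate data sets are flagged", {
  withr::local_seed(18)
  noAlertHigh <- makePairSet(list(
    BG_LOW = 2, BG_HIGH = 2, ALERT_LOW = 2, NEUTRAL = 20
  ))
  expect_warning(res <- eliminatePairs(noAlertHigh), "critical region")
  expect_false(res@feasible)
  expect_equal(res@k, 0)

  # far-out neutral pairs (all D > 1) force an inadequate exclusion
  farNeutral <- do.call(rbind, lapply(1:20, function(i) {
    data.frame(
      subject_id = "S", session_id = "X", time_min = i * 15,
      bg = 292, roc = 1.2, dt = 15, valid_interval = TRUE, index = i
    )
  }))
  crit <- pairData(makePairSet(list(
    BG_LOW = 2, BG_HIGH = 2, ALERT_LOW = 2, ALERT_HIGH = 2
  )))
  crit$index <- crit$index + 20
  ps <- PairSet(rbind(farNeutral, crit))
  expect_warning(res2 <- eliminatePairs(ps), "inadequate")
  expect_false(res2@adequate)
  expect_true(res2@feasible)
  expect_gt(res2@maxExcludedD, 1)
  expect_true(isCompliant(res2@after))
})

test_that("greedy k equals the exhaustive minimal k on random instances", {
  withr::local_seed(99)
  for (i in 1:1000) {
    counts <- list(
      BG_LOW = sample(0:6, 1), BG_HIGH = sample(0:6, 1),
      ALERT_LOW = sample(0:6, 1), ALERT_HIGH = sample(0:6, 1),
      NEUTRAL = sample(0:40, 1)
    )
    if (sum(unlist(counts)) == 0 || sum(unlist(counts)) > 60) next
    expected <- oracleMinExclusions(counts)
    rep <- distributionReport(makePairSet(counts))
    expect_equal(minExclusions(rep), expected, label = paste(unlist(counts), collapse = ","))
    if (is.finite(expected)) {
      res <- suppressWarnings(eliminatePairs(makePairSet(counts)))
      expect_equal(res@k, expected)
      expect_true(isCompliant(res@after) || expected == 0)
    }
  }
})

test_that("adding a neutral pair never decreases the required exclusions", {
  withr::local_seed(55)
  for (i in 1:50) {
    counts <- list(
      BG_LOW = sample(1:4, 1), BG_HIGH = sample(1:4, 1),
      ALERT_LOW = sample(1:4, 1), ALERT_HIGH = sample(1:4, 1),
      NEUTRAL = sample(5:30, 1)
    )
    k1 <- oracleMinExclusions(counts)
    counts2 <- counts
    counts2$NEUTRAL <- counts$NEUTRAL + 1
    k2 <- oracleMinExclusions(counts2)
    expect_gte(k2, k1)
    rep1 <- distributionReport(makePairSet(counts))
    rep2 <- distributionReport(makePairSet(counts2))
    expect_gte(minExclusions(rep2), minExclusions(rep1))
  }
})
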