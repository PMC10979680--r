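test_that("region classification matches the region definitions point-wise", {
  cases <- list(
    list(60, 2, "BG_LOW"), # below 70: any RoC
    list(310, -2, "BG_HIGH"), # above 300: any RoC
    list(90, -1.5, "ALERT_LOW"), # 90 - 45 = 45 < 70
    list(150, -1.5, "NEUTRAL"), # 150 - 45 = 105, projection fails
    list(150, -3, "ALERT_LOW"), # 150 - 90 = 60 < 70
    list(200, 2, "ALERT_HIGH"), # 200 + 60 = 260 > 250
    list(200, 1.6, "NEUTRAL"), # 200 + 48 = 248, projection fails
    list(70, 0, "NEUTRAL") # no strict inequality satisfied
  )
  for (cs in cases) {
    expect_equal(
      as.character(classifyRoCBG(cs[[1]], cs[[2]])), cs[[3]],
      label = sprintf("bg=%g roc=%g", cs[[1]], cs[[2]])
    )
  }
})

test_that("boundary points fall to NEUTRAL (strict inequalities)", {
  boundary <- rbind(
    c(70, 0), # bg exactly 70: not BG_LOW (strict)
    c(300, 0), # bg exactly 300: not BG_HIGH (strict)
    c(150, -1), # roc exactly -1: not ALERT_LOW (strict)
    c(205, 1.5), # roc exactly +1.5: not ALERT_HIGH (strict)
    c(100, -1), # projection exactly 70 at the tilt anchor
    c(220, 1) # projection exactly 250
  )
  labels <- as.character(classifyRoCBG(boundary[, 1], boundary[, 2]))
  expect_equal(labels, rep("NEUTRAL", 6))
  # but the bg >= 70 edge of ALERT_LOW is non-strict
  expect_equal(as.character(classifyRoCBG(70, -5)), "ALERT_LOW")
  expect_equal(as.character(classifyRoCBG(300, 5)), "ALERT_HIGH")
  expect_error(classifyRoCBG(NaN, 0), "finite")
})

test_that("the five regions partition the plane", {
  grid <- expand.grid(
    bg = seq(20, 450, length.out = 120),
    roc = seq(-6, 6, length.out = 120)
  )
  labels <- classifyRoCBG(grid$bg, grid$roc)
  preds <- t(mapply(independentRegionPredicates, grid$bg, grid$roc))
  expect_true(all(rowSums(preds) == 1))
  expect_true(all(preds[cbind(seq_len(nrow(grid)), as.integer(labels))]))
})

test_that("alert boundaries meet their tilt anchors", {
  # ALERT_LOW tilted border (70 - bg)/30 equals the flat -1 at bg = 100
  expect_equal((70 - 100) / 30, -1)
  # just below bg = 100 the tilted border governs; just above, the flat -1:
  # at bg = 100 a RoC marginally past -1 already projects below 70
  expect_equal(as.character(classifyRoCBG(100, -1.001)), "ALERT_LOW")
  expect_equal(as.character(classifyRoCBG(101, -1.001)), "NEUTRAL")
  # ALERT_HIGH tilted border (250 - bg)/30 equals the flat +1.5 at bg = 205
  expect_equal((250 - 205) / 30, 1.5)
  expect_equal(as.character(classifyRoCBG(205, 1.501)), "ALERT_HIGH")
  expect_equal(as.character(classifyRoCBG(204, 1.501)), "NEUTRAL")
})

test_that("classification is invariant under exact unit conversion", {
  withr::local_seed(5)
  bg <- runif(500, 20, 450)
  roc <- runif(500, -6, 6)
  f <- MGDL_PER_MMOLL
  cfgMmol <- RegionConfig(
    bgLow = 70 / f, bgHigh = 300 / f, hypoTarget = 70 / f,
    hyperTarget = 250 / f, horizon = 30, alertLowRoC = -1 / f,
    alertHighRoC = 1.5 / f
  )
  expect_equal(
    classifyRoCBG(bg, roc),
    classifyRoCBG(bg / f, roc / f, cfgMmol)
  )
})

test_that("distribution report counts, compliance and the exact 7.5% boundary", {
  r1 <- distributionReport(makePairSet(list(
    BG_LOW = 2, BG_HIGH = 2, ALERT_LOW = 2, ALERT_HIGH = 2
  )))
  expect_true(isCompliant(r1))
  expect_equal(unname(regionFractions(r1)[criticalRegions()]), rep(0.25, 4))

  withr::local_seed(8)
  r2 <- distributionReport(makePairSet(list(
    BG_LOW = 2, BG_HIGH = 2, ALERT_LOW = 2, ALERT_HIGH = 2, NEUTRAL = 20
  )))
  expect_false(isCompliant(r2)) # 2/28 < 7.5%
  expect_equal(sum(regionCounts(r2)), 28)

  r3 <- distributionReport(makePairSet(list(
    BG_LOW = 3, BG_HIGH = 3, ALERT_LOW = 3, ALERT_HIGH = 3, NEUTRAL = 28
  )))
  expect_true(isCompliant(r3)) # 3/40 is exactly 7.5%, inclusive

  # fractions sum to one; a compliant report can never have neutral > 70%
  expect_equal(sum(regionFractions(r3)), 1)
  expect_lte(regionFractions(r3)[["NEUTRAL"]], 0.70)
})

test_that("shortfall counts the pairs needed to reach the minimum", {
  withr::local_seed(9)
  r <- distributionReport(makePairSet(list(
    BG_LOW = 1, BG_HIGH = 3, ALERT_LOW = 3, ALERT_HIGH = 3, NEUTRAL = 30
  )))
  s <- r@shortfall[["BG_LOW"]]
  # adding s BG_LOW pairs reaches compliance, s - 1 does not
  n <- 40
  expect_true((1 + s) / (n + s) >= 0.075)
  expect_false((1 + s - 1) / (n + s - 1) >= 0.075)
})
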