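# helper: build a 5-min trace from a glucose vector
trace5 <- function(g, id = "T1", t0 = 0) {
  CGMTrace(id, time = seq(t0, by = 5, length.out = length(g)), glucose = g)
}

test_that("episode detection applies the duration inclusion rules exactly", {
  # 4 consecutive readings < 70 span 15 min: included
  tr <- trace5(c(rep(100, 13), rep(60, 4), rep(100, 5)))
  ep <- detectEpisodes(tr, kind = "hypo")
  expect_equal(nrow(ep), 1)
  expect_true(ep$included)
  expect_equal(ep$duration, 15)
  expect_equal(ep$n_samples, 4)

  # 3 consecutive readings span only 10 min: excluded as too short
  ep2 <- detectEpisodes(trace5(c(rep(100, 13), rep(60, 3), rep(100, 5))), kind = "hypo")
  expect_false(ep2$included)
  expect_equal(ep2$exclusion_reason, "too_short")

  # 30 consecutive readings span 145 min: detected but excluded as too long
  ep3 <- detectEpisodes(trace5(c(rep(100, 13), rep(60, 30), rep(100, 5))), kind = "hypo")
  expect_equal(nrow(ep3), 1)
  expect_false(ep3$included)
  expect_equal(ep3$duration, 145)
  expect_equal(ep3$exclusion_reason, "too_long")

  # all-in-range trace yields an empty table
  expect_equal(nrow(detectEpisodes(trace5(rep(120, 30)), kind = "hypo")), 0)

  # hyper episodes mirror the rules above the 250 mg/dL threshold
  ep4 <- detectEpisodes(trace5(c(rep(200, 13), rep(260, 4), rep(200, 5))), kind = "hyper")
  expect_true(ep4$included)
  expect_equal(ep4$duration, 15)
})

test_that("episode runs are maximal, separated, and broken at gaps", {
  g <- c(rep(100, 13), rep(60, 4), 80, rep(65, 5), rep(100, 4))
  ep <- detectEpisodes(trace5(g), kind = "hypo")
  expect_equal(nrow(ep), 2) # one in-range sample separates episodes
  # every sample inside a detected run is beyond the threshold
  for (i in seq_len(nrow(ep))) {
    expect_true(all(g[ep$start_idx[i]:ep$end_idx[i]] < 70))
  }
  # a sampling gap breaks a run
  tr <- CGMTrace("G", time = c(seq(0, 60, 5), seq(75, 120, 5)),
                 glucose = c(rep(100, 10), rep(60, 3), rep(60, 4), rep(100, 6)))
  epG <- detectEpisodes(tr, kind = "hypo")
  expect_equal(nrow(epG), 2)
  # irregular off-grid sampling is rejected
  bad <- CGMTrace("B", time = c(0, 5, 12, 17), glucose = rep(60, 4))
  expect_error(detectEpisodes(bad, kind = "hypo"), "non-uniform")
})

test_that("pre-episode qualification needs a complete monotone in-range hour", {
  pre <- seq(130, 72, length.out = 12) # strictly decreasing, >= 70
  ok <- trace5(c(rep(135, 3), pre, rep(60, 4), rep(100, 4)))
  ep <- detectEpisodes(ok, kind = "hypo")
  expect_true(ep$qualified)

  # one +1 mg/dL uptick in the hour disqualifies
  preUp <- pre
  preUp[6] <- preUp[5] + 1
  epUp <- detectEpisodes(trace5(c(rep(135, 3), preUp, rep(60, 4), rep(100, 4))),
                         kind = "hypo")
  expect_false(epUp$qualified)
  expect_equal(epUp$disqualification_reason, "not_monotone")

  # a brief sub-70 dip inside the hour disqualifies the main episode
  preLow <- pre
  preLow[4] <- 65 # one-sample dip, itself too short to be an episode
  epLow <- detectEpisodes(trace5(c(rep(135, 3), preLow, rep(60, 4), rep(100, 4))),
                          kind = "hypo")
  main <- epLow[epLow$included, ]
  expect_equal(nrow(main), 1)
  expect_false(main$qualified)
  expect_equal(main$disqualification_reason, "lookback_below_threshold")

  # flat segments are allowed (RoC <= 0 is non-strict)
  preFlat <- c(rep(120, 6), seq(118, 80, length.out = 6))
  epFlat <- detectEpisodes(trace5(c(rep(125, 3), preFlat, rep(60, 4), rep(100, 4))),
                           kind = "hypo")
  expect_true(epFlat$qualified)

  # an episode starting before a full hour of data cannot qualify
  epShort <- detectEpisodes(trace5(c(seq(100, 75, length.out = 6), rep(60, 4), rep(100, 4))),
                            kind = "hypo")
  expect_false(epShort$qualified)
  expect_equal(epShort$disqualification_reason, "incomplete_lookback")
})

test_that("aligned summary computes nested percentiles on the derived example", {
  episodes <- data.frame(
    subject_id = c("A", "B"), included = TRUE, qualified = TRUE,
    start_time = c(100, 100), stringsAsFactors = FALSE
  )
  traces <- list(
    A = CGMTrace("A", seq(0, 200, 5), rep(100, 41)),
    B = CGMTrace("B", seq(0, 200, 5), rep(200, 41))
  )
  s <- alignedSummary(episodes, traces)
  expect_equal(unique(s$p50), 150)
  expect_equal(unique(s$p5), 100) # linear interpolation clamps at n = 2
  expect_equal(unique(s$p95), 200)
  expect_equal(unique(s$n), 2L)

  # identical traces: all bands coincide with the trace
  episodes10 <- data.frame(
    subject_id = sprintf("S%d", 1:10), included = TRUE, qualified = TRUE,
    start_time = 100, stringsAsFactors = FALSE
  )
  g <- seq(200, 100, length.out = 41)
  traces10 <- stats::setNames(
    lapply(sprintf("S%d", 1:10), function(id) CGMTrace(id, seq(0, 200, 5), g)),
    sprintf("S%d", 1:10)
  )
  s10 <- alignedSummary(episodes10, traces10)
  at <- match(s10$offset_min + 100, seq(0, 200, 5))
  for (col in c("p5", "p25", "p50", "p75", "p95")) {
    expect_equal(s10[[col]], g[at])
  }
})

test_that("percentile bands are nested on random inputs", {
  withr::local_seed(77)
  episodes <- data.frame(
    subject_id = sprintf("R%d", 1:25), included = TRUE, qualified = TRUE,
    start_time = 100, stringsAsFactors = FALSE
  )
  traces <- stats::setNames(
    lapply(sprintf("R%d", 1:25), function(id) {
      CGMTrace(id, seq(0, 200, 5), runif(41, 50, 350))
    }),
    sprintf("R%d", 1:25)
  )
  s <- alignedSummary(episodes, traces)
  expect_true(all(s$p5 <= s$p25 & s$p25 <= s$p50 &
                    s$p50 <= s$p75 & s$p75 <= s$p95))
})

test_that("aligned summary recovers a known median descent from noisy traces", {
  withr::local_seed(123)
  n <- 60
  ids <- sprintf("N%02d", 1:n)
  curve <- c(rep(135, 3), seq(130, 74, length.out = 12), rep(60, 5), seq(70, 110, length.out = 8))
  traces <- stats::setNames(lapply(ids, function(id) {
    CGMTrace(id, seq(0, by = 5, length.out = length(curve)),
             pmax(45, curve + rnorm(1, 0, 5))) # per-trace level shift
  }), ids)
  eps <- do.call(rbind, lapply(ids, function(id) {
    e <- detectEpisodes(traces[[id]], kind = "hypo")
    if (nrow(e)) e else NULL
  }))
  eps <- eps[eps$included & eps$qualified, ]
  expect_gt(nrow(eps), 35)
  s <- alignedSummary(eps, traces, window = c(-60, 20))
  at <- s$offset_min == -30
  trueVal <- curve[16 - 6] # episode starts at index 16; -30 min = 6 samples back
  expect_lt(abs(s$p50[at] - trueVal), 3)
})

test_that("DGR projection of summary curves uses difference-quotient RoC", {
  s <- data.frame(offset_min = seq(-60, 0, 5), p50 = rep(150, 13))
  proj <- projectSummaryToDGR(s, smoothWindow = 1)
  expect_equal(proj$roc, rep(0, 12))

  s2 <- data.frame(offset_min = seq(-60, 0, 5), p50 = seq(220, 100, by = -10))
  proj2 <- projectSummaryToDGR(s2, smoothWindow = 1)
  expect_equal(proj2$roc, rep(-2, 12))
  # smoothing window 1 is the identity; window 3 preserves a linear curve's
  # interior values
  proj3 <- projectSummaryToDGR(s2, smoothWindow = 3)
  expect_equal(proj3$roc[2:11], rep(-2, 10))
  expect_equal(proj3$bg[2:11], proj2$bg[2:11])
})

test_that("constructed descent cohort recovers the designed alert-low traversal rate", {
  withr::local_seed(202)
  cohort <- generateDescentCohort(400, probSteep = 0.5)
  traverses <- vapply(names(cohort$traces), function(id) {
    tr <- cohort$traces[[id]]
    ep <- detectEpisodes(tr, kind = "hypo")
    ep <- ep[ep$included & ep$qualified, ]
    expect_equal(nrow(ep), 1)
    # classify the RoC-BG pairs of the 60-min lookback
    pre <- pairData(computePairs(tr))
    pre <- pre[pre$time_min <= ep$start_time & pre$time_min > ep$start_time - 60, ]
    any(classifyRoCBG(pre$bg, pre$roc) == "ALERT_LOW")
  }, logical(1))
  # steep traces traverse ALERT_LOW by construction, shallow ones never do
  expect_equal(unname(traverses), unname(cohort$steep))
  # the traversal fraction recovers the 50% design within binomial error
  phat <- mean(traverses)
  expect_lt(abs(phat - 0.5), 3 * sqrt(0.25 / 400))
})
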