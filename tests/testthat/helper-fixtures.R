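# Fixture builders used across tests. All fixtures are generated in code.

# draw one (bg, roc) point guaranteed to lie in the given DGR region
randomRegionPoint <- function(region) {
  switch(region,
    BG_LOW = c(bg = runif(1, 20, 69.5), roc = runif(1, -5, 5)),
    BG_HIGH = c(bg = runif(1, 300.5, 450), roc = runif(1, -5, 5)),
    ALERT_LOW = {
      bg <- runif(1, 70, 250)
      roc <- min(-1, (70 - bg) / 30) - runif(1, 0.1, 3)
      c(bg = bg, roc = roc)
    },
    ALERT_HIGH = {
      bg <- runif(1, 70, 300)
      roc <- max(1.5, (250 - bg) / 30) + runif(1, 0.1, 3)
      c(bg = bg, roc = roc)
    },
    NEUTRAL = c(bg = runif(1, 70.5, 299.5), roc = runif(1, -0.9, 1.4))
  )
}

# build a PairSet with the requested number of pairs per region
makePairSet <- function(counts) {
  regions <- rep(names(counts), unlist(counts))
  pts <- t(vapply(regions, randomRegionPoint, numeric(2)))
  n <- nrow(pts)
  ps <- PairSet(data.frame(
    subject_id = "SIM", session_id = "X",
    time_min = seq_len(n) * 15, bg = pts[, "bg"], roc = pts[, "roc"],
    dt = 15, valid_interval = TRUE, index = seq_len(n),
    stringsAsFactors = FALSE
  ))
  stopifnot(identical(
    as.character(classifyPairs(ps)$region), regions
  ))
  ps
}

# independent oracle for the minimal number of neutral exclusions: removing
# any k neutral pairs leaves critical counts unchanged, so scan k upward and
# test compliance of the shrunken set directly
oracleMinExclusions <- function(counts, minFrac = 0.075) {
  crit <- unlist(counts[c("BG_LOW", "BG_HIGH", "ALERT_LOW", "ALERT_HIGH")])
  if (any(crit == 0)) {
    return(Inf)
  }
  n <- sum(unlist(counts))
  for (k in 0:counts$NEUTRAL) {
    if (all(crit / (n - k) >= minFrac)) {
      return(k)
    }
  }
  Inf
}

# five-region predicates written down independently of the package's ordered
# implementation (used for the partition property)
independentRegionPredicates <- function(bg, roc) {
  projection <- bg + 30 * roc
  c(
    BG_LOW = bg < 70,
    BG_HIGH = bg > 300,
    ALERT_LOW = bg >= 70 & bg <= 300 & roc < -1 & projection < 70,
    ALERT_HIGH = bg >= 70 & bg <= 300 & roc > 1.5 & projection > 250,
    NEUTRAL = !(bg < 70) & !(bg > 300) &
      !(bg >= 70 & roc < -1 & projection < 70) &
      !(roc > 1.5 & projection > 250)
  )
}
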