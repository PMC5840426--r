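test_that("cyclone ramp steps at impact and decays linearly to zero", {
  s <- CycloneSchedule(23L)
  expect_equal(cycloneRamp(23, s), 1)
  expect_equal(cycloneRamp(23 + 12, s), 0)
  expect_equal(cycloneRamp(23 + 6, s), 0.5)
  expect_equal(cycloneRamp(10, s), 0)   # before impact
  expect_equal(cycloneRamp(200, s), 0)  # long after
  # linear interpolation oracle at every month of the ramp
  k <- 0:12
  expect_equal(cycloneRamp(23 + k, s), pmax(0, 1 - k / 12))
})

test_that("overlapping ramps take the maximum; indicator variant is flat", {
  s <- CycloneSchedule(c(10L, 14L))
  expect_equal(cycloneRamp(14, s), 1)                  # second impact
  expect_equal(cycloneRamp(16, s), max(1 - 6 / 12, 1 - 2 / 12))
  ind <- CycloneSchedule(10L, useRamp = FALSE)
  expect_equal(cycloneRamp(c(10, 15, 21, 22), ind), c(1, 1, 1, 0))
})

test_that("seasonal proportion peaks in December and dips in June", {
  # alpha solved from the 86%/30% December/June proportions
  a2 <- 2 / (0.86 - 0.30)
  a1 <- 0.86 * a2 - 1
  p <- SsmParams(alpha1 = a1, alpha2 = a2)
  # with a May start, month 8 is December and month 2 is June
  expect_equal(seasonalProportion(8, p), 0.86, tolerance = 1e-12)
  expect_equal(seasonalProportion(2, p), 0.30, tolerance = 1e-12)
  # closed forms (alpha1 + 1)/alpha2 and (alpha1 - 1)/alpha2
  expect_equal(seasonalProportion(8, p), (a1 + 1) / a2)
  expect_equal(seasonalProportion(2, p), (a1 - 1) / a2)
  # cyclone at the queried month scales availability by 1 - cR
  s <- CycloneSchedule(8L)
  expect_equal(seasonalProportion(8, p, s), 0.86 * (1 - 0.24))
  expect_error(seasonalProportion(1, SsmParams(alpha1 = 0.5, alpha2 = 3)),
               "alpha")
})

test_that("over a cyclone-free year availability is extremal in Dec/June", {
  p <- truthParams()
  for (startCM in c(1L, 5L, 9L)) {
    t <- 1:12
    vals <- seasonalProportion(t, p, startCalendarMonth = startCM)
    cm <- calendarMonthAt(t, startCM)
    expect_equal(cm[which.max(vals)], 12L)
    expect_equal(cm[which.min(vals)], 6L)
    expect_equal(max(vals) - min(vals), 2 / p@alpha2, tolerance = 1e-12)
  }
})

test_that("recruitment is confined to Dec-Feb and penalized once", {
  p <- truthParams()
  s <- CycloneSchedule(23L)  # March of year 2 on a May start
  t <- 1:60
  cm <- calendarMonthAt(t, 5L)
  r <- recruitmentRate(t, p, s)
  expect_true(all(r[!cm %in% c(12, 1, 2)] == 0))
  # season before the cyclone (Dec yr1 = month 8) is unaffected
  expect_equal(r[8], p@rho)
  # first season after (Dec yr3 = month 32) carries cRho, all 3 months
  expect_equal(r[32:34], rep(p@rho * p@cRho, 3))
  # following season is back to normal
  expect_equal(r[44], p@rho)
})

test_that("mortality carries the ramped multiplicative excess", {
  p <- truthParams()
  s <- CycloneSchedule(23L)
  expect_equal(mortalityRate(10, p, s), 0.017)
  expect_equal(mortalityRate(23, p, s), 0.017 * 5.7, tolerance = 1e-12)
  expect_equal(mortalityRate(23, p, s), 0.0969, tolerance = 1e-4)
  expect_equal(mortalityRate(23 + 6, p, s),
               0.017 * (1 + 4.7 * 0.5), tolerance = 1e-12)
  expect_equal(mortalityRate(23 + 12, p, s), 0.017)  # fully recovered
  pNoEff <- truthParams(); pNoEff@cMu <- 1
  expect_identical(mortalityRate(23, pNoEff, s), pNoEff@mu)
})

test_that("prior support matches the stated bounds (boundary +/- eps)", {
  expect_true(is.finite(logPrior(truthParams())))
  eps <- 1e-8
  bad <- list(
    function(p) { p@rho <- 0.11 + eps; p },
    function(p) { p@mu <- 0.1 + eps; p },
    function(p) { p@cMu <- 1 - eps; p },
    function(p) { p@cMu <- 0.5; p },
    function(p) { p@sigmaObs <- 0.05 - eps; p },
    function(p) { p@sigmaObs <- 0.47 + eps; p },
    function(p) { p@sigmaProc <- 10 + eps; p },
    function(p) { p@alpha1 <- 1 - 1e-4; p },
    function(p) { p@alpha2 <- p@alpha1 + 1 - eps; p },
    function(p) { p@sigmaCamp <- 100 + eps; p })
  for (f in bad) expect_identical(logPrior(f(truthParams())), -Inf)
  good <- list(
    function(p) { p@rho <- 0.11 - eps; p },
    function(p) { p@mu <- 0.1 - eps; p },
    function(p) { p@cMu <- 1 + eps; p },
    function(p) { p@sigmaObs <- 0.05 + eps; p },
    function(p) { p@alpha1 <- 1 + eps; p })
  for (f in good) expect_true(is.finite(logPrior(f(truthParams()))))
})

test_that("prior bounds encode the stated demographic beliefs", {
  # mu upper bound: a 70% reduction over 12 months
  expect_equal(exp(-12 * 0.1), 0.301, tolerance = 1e-3)
  # rho upper bound: a 40% increase over a 3-month season
  expect_equal(exp(3 * 0.11) - 1, 0.391, tolerance = 1e-3)
})

test_that("log joint equals the independent term-by-term oracle", {
  st <- tinyStates(); pa <- truthParams()
  da <- tinyData(); sc <- tinySchedule()
  expect_equal(logJoint(st, pa, da, sc), oracleLogJoint(st, pa, da, sc),
               tolerance = 1e-10)
  # and on a cyclone-free version with different parameters
  pa2 <- SsmParams(rho = 0.05, mu = 0.03, cRho = 0.5, cMu = 2, cR = 0.1,
                   alpha1 = 3, alpha2 = 6, sigmaProc = 0.3,
                   sigmaCamp = 0.2, sigmaObs = 0.12)
  expect_equal(logJoint(st, pa2, da, CycloneSchedule()),
               oracleLogJoint(st, pa2, da, CycloneSchedule()),
               tolerance = 1e-10)
})

test_that("log joint handles missing months and degenerate inputs", {
  st <- tinyStates(); pa <- truthParams()
  da <- tinyData(); sc <- tinySchedule()
  # missing month 3 contributes no observation term: perturbing y there
  # is impossible (NA), but removing the observed flag from month 4
  # drops exactly its observation term
  da2 <- da; da2@observed[4] <- FALSE; da2@y[4] <- NA
  drop4 <- dlnorm(da@y[4], log(st@inCamp[4]), pa@sigmaObs, log = TRUE)
  expect_equal(logJoint(st, pa, da2, sc), logJoint(st, pa, da, sc) - drop4,
               tolerance = 1e-10)
  # non-positive states give -Inf
  stBad <- tinyStates(); stBad@total[2] <- -1
  expect_identical(suppressWarnings(logJoint(stBad, pa, da, sc)), -Inf)
  # shape mismatch signals
  expect_error(logJoint(LatentTrajectory(1:3, 1:3), pa, da, sc), "same")
  # out-of-support parameters give -Inf
  paBad <- truthParams(); paBad@cMu <- 0.5
  expect_identical(logJoint(st, paBad, da, sc), -Inf)
})

test_that("observation terms at zero residual decrease as sigma doubles", {
  pa <- truthParams()
  da <- tinyData(); sc <- tinySchedule()
  st <- tinyStates()
  st@inCamp[da@observed] <- da@y[da@observed]  # zero observation residual
  pa2 <- pa; pa2@sigmaObs <- 2 * pa@sigmaObs
  expect_lt(logJoint(st, pa2, da, sc), logJoint(st, pa, da, sc))
})

test_that("transition log-mean is monotone in the rates", {
  pa <- truthParams()
  t <- 33  # a December under the May start
  g1 <- recruitmentRate(t, pa) - mortalityRate(t, pa)
  paUp <- pa; paUp@rho <- pa@rho + 0.01
  expect_gt(recruitmentRate(t, paUp) - mortalityRate(t, paUp), g1)
  paMu <- pa; paMu@mu <- pa@mu + 0.01
  expect_lt(recruitmentRate(t, paMu) - mortalityRate(t, paMu), g1)
})

test_that("neutral cyclone parameters reproduce the empty schedule bitwise", {
  pa <- truthParams()
  pa@cMu <- 1; pa@cRho <- 1; pa@cR <- 0
  s <- CycloneSchedule(c(23L, 82L, 106L))
  none <- CycloneSchedule()
  t <- 1:154
  expect_identical(seasonalProportion(t, pa, s), seasonalProportion(t, pa, none))
  expect_identical(recruitmentRate(t, pa, s), recruitmentRate(t, pa, none))
  expect_identical(mortalityRate(t, pa, s), mortalityRate(t, pa, none))
  st <- tinyStates(); da <- tinyData()
  expect_identical(logJoint(st, pa, da, tinySchedule()),
                   logJoint(st, pa, da, none))
})
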