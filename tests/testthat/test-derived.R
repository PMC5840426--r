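# build a PosteriorDraws by hand so derived quantities can be tested
# against known parameter values and states
fakeDraws <- function(parRows, states = NULL, nMonths = 30,
                      startCM = 5L, schedule = CycloneSchedule()) {
  m <- do.call(rbind, parRows)
  colnames(m) <- names(parRows[[1]])
  nd <- nrow(m)
  if (is.null(states))
    states <- matrix(log(1000), nd, nMonths)
  y <- rep(500, nMonths)
  data <- CountSeries(y, startCalendarMonth = startCM)
  new("PosteriorDraws", paramDraws = list(m),
      totalDraws = list(states), inCampDraws = list(states - 1),
      stateIterations = seq_len(nd),
      acceptance = list(), rhat = setNames(numeric(0), character(0)),
      config = McmcConfig(nChains = 1, nIter = nd, thinStates = 1),
      data = data, schedule = schedule)
}

truthRow <- function(...) {
  v <- truthVector()
  over <- list(...)
  v[names(over)] <- unlist(over)
  v
}

test_that("skeleton rate reduces to the closed form without cyclones", {
  expect_equal(skeletonRate(SsmParams(rho = 0, mu = 0), 0), 0)
  expect_equal(skeletonRate(SsmParams(rho = 0.068, mu = 0.017), 0), 0,
               tolerance = 1e-12)
  set.seed(42)
  for (i in 1:100) {
    p <- SsmParams(rho = runif(1, 0, 0.11), mu = runif(1, 0, 0.1),
                   cRho = runif(1), cMu = runif(1, 1, 10))
    expect_equal(skeletonRate(p, 0), 3 * p@rho - 12 * p@mu,
                 tolerance = 1e-12)
  }
})

test_that("skeleton rate with cyclones matches the per-event decrement", {
  # closed-form oracle: each event adds 6.5 ramp-months of excess
  # mortality and one breeding season at reduced recruitment
  p <- truthParams()
  f <- 3 / 12.8
  oracle <- (3 * p@rho - 12 * p@mu) -
    f * (p@mu * (p@cMu - 1) * 6.5 + 3 * p@rho * (1 - p@cRho))
  expect_equal(skeletonRate(p, f), oracle, tolerance = 1e-12)
  expect_equal(skeletonRate(p, f), -0.1318, tolerance = 1e-3)
  expect_error(skeletonRate(p, -1), "non-negative")
})

test_that("rate of increase is monotone in cyclone frequency", {
  p <- truthParams()
  fs <- seq(0, 1, by = 0.1)
  rs <- vapply(fs, function(f) skeletonRate(p, f), numeric(1))
  expect_true(all(diff(rs) < 0))
  # with neutral cyclone effects the frequency is irrelevant
  pn <- truthParams(); pn@cMu <- 1; pn@cRho <- 1
  expect_equal(skeletonRate(pn, 0.5), skeletonRate(pn, 0))
})

test_that("posterior rates respect the draw-wise ordering invariant", {
  set.seed(9)
  rows <- lapply(1:200, function(i)
    truthRow(rho = runif(1, 0, 0.11), mu = runif(1, 0, 0.1),
             cMu = runif(1, 1, 10), cRho = runif(1)))
  dr <- fakeDraws(rows)
  rates <- rateOfIncrease(dr, cycloneFrequency = 0.25)
  expect_true(all(rates@rWithCyclone <= rates@rNoCyclone + 1e-12))
  expect_equal(rates@rNoCyclone,
               vapply(rows, function(v) 3 * v[["rho"]] - 12 * v[["mu"]],
                      numeric(1)))
  expect_gte(rates@pDecline, 0); expect_lte(rates@pDecline, 1)
})

test_that("default cyclone frequency is the observed one", {
  dr <- fakeDraws(list(truthRow()), nMonths = 154,
                  schedule = CycloneSchedule(c(23L, 82L, 106L)))
  rates <- rateOfIncrease(dr)
  expect_equal(rates@cycloneFrequency, 3 / (154 / 12))
})

test_that("probability of decline equals the empirical cdf at zero", {
  expect_equal(probDecline(c(-1, -2, -0.5)), 1)
  set.seed(4)
  r <- rnorm(4000, 0, 1)
  expect_equal(probDecline(r), mean(ecdf(r)(0) ), tolerance = 1e-9)
  expect_lt(abs(probDecline(r) - 0.5), 0.03)
  # normal-CDF oracle around the declining-population posterior
  rr <- rnorm(200000, -0.12, 0.127)
  expect_equal(probDecline(rr), pnorm(0.12 / 0.127), tolerance = 0.01)
  expect_equal(pnorm(0.12 / 0.127), 0.83, tolerance = 0.01)
})

test_that("November summaries are ordered quantiles of the state draws", {
  set.seed(5)
  rows <- lapply(1:50, function(i) truthRow())
  states <- matrix(rnorm(50 * 30, log(1000), 0.2), 50, 30)
  dr <- fakeDraws(rows, states = states)
  s <- novemberSummary(dr)
  # May start, 30 months: Novembers at 7 and 19
  expect_equal(s$monthIndex, c(7L, 19L))
  expect_true(all(s$totalLower <= s$totalMedian))
  expect_true(all(s$totalMedian <= s$totalUpper))
  expect_equal(s$totalMedian[1], median(exp(states[, 7])), tolerance = 1e-9)
  # degenerate draws collapse the interval
  dr0 <- fakeDraws(rows, states = matrix(log(1000), 50, 30))
  s0 <- novemberSummary(dr0)
  expect_equal(s0$totalUpper - s0$totalLower, rep(0, 2))
  # series without Novembers signals
  drShort <- fakeDraws(rows, states = matrix(log(10), 50, 3), nMonths = 3,
                       startCM = 1L)
  expect_error(novemberSummary(drShort), "November")
})

test_that("percent decline matches the draw-wise ratio", {
  states <- rbind(log(c(1000, 800)), log(c(2000, 1000)))
  dr <- fakeDraws(list(truthRow(), truthRow()), states = states,
                  nMonths = 2)
  expect_equal(percentDecline(dr, 1, 2),
               median(c(100 * (1 - 0.8), 100 * (1 - 0.5))))
})

test_that("projections respond to cyclones and handle edge horizons", {
  set.seed(6)
  rows <- lapply(1:400, function(i) truthRow())
  states <- matrix(rnorm(400 * 24, log(100000), 0.05), 400, 24)
  dr <- fakeDraws(rows, states = states, nMonths = 24)
  p0 <- projectPopulation(dr, 0)
  expect_equal(nrow(p0$total), 1)
  expect_equal(p0$total$median, median(exp(states[, 24])), tolerance = 1e-9)
  # an immediate cyclone depresses the projected medians
  pNo <- projectPopulation(dr, 18, seed = 3)
  pCy <- projectPopulation(dr, 18,
                           futureSchedule = CycloneSchedule(25L), seed = 3)
  expect_true(all(pCy$total$median[3:18] < pNo$total$median[3:18]))
  expect_error(projectPopulation(dr, -1), "non-negative")
})

test_that("zero-noise parameter draws give a flat projection", {
  v <- truthRow(rho = 0, mu = 0)
  v[["sigmaProc"]] <- 1e-12; v[["sigmaCamp"]] <- 1e-12
  dr <- fakeDraws(list(v), states = matrix(log(1000), 1, 24), nMonths = 24)
  pr <- projectPopulation(dr, 12, seed = 1)
  expect_equal(pr$total$median, rep(1000, 12), tolerance = 1e-6)
})
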