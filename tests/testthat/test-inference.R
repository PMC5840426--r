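test_that("Gelman-Rubin diagnostic matches a brute-force oracle", {
  set.seed(1)
  chains <- list(matrix(rnorm(600), ncol = 3),
                 matrix(rnorm(600), ncol = 3),
                 matrix(rnorm(600), ncol = 3))
  got <- gelmanRubin(chains)
  # independent computation of sqrt((n-1)/n + B/(n W)) per column
  oracle <- sapply(1:3, function(j) {
    draws <- sapply(chains, function(m) m[, j])
    n <- nrow(draws)
    W <- mean(apply(draws, 2, var))
    B <- n * var(colMeans(draws))
    max(1, sqrt((n - 1) / n + B / (n * W)))
  })
  expect_equal(unname(got), oracle, tolerance = 1e-12)
})

test_that("Gelman-Rubin flags separated chains and passes identical ones", {
  set.seed(2)
  a <- matrix(rnorm(500), ncol = 1)
  expect_equal(unname(gelmanRubin(list(a, a))), 1)
  b <- matrix(rnorm(500, 100), ncol = 1)
  expect_gt(gelmanRubin(list(a, b))[1], 1.2)
  # oracle: sqrt(499/500 + 500*var(c(0,100)-ish means)/500) ~ 70
  expect_gt(gelmanRubin(list(a, b))[1], 50)
  expect_error(gelmanRubin(list(a)), "two chains")
  expect_error(gelmanRubin(list(a[1:5, , drop = FALSE],
                                b[1:5, , drop = FALSE])), "10")
})

test_that("chain initialization is finite, data-guided and overdispersed", {
  d <- simulateScenario(defaultScenario(seed = 6))
  i1 <- initializeChain(d@counts, d@scenario@schedule, seed = 1)
  i2 <- initializeChain(d@counts, d@scenario@schedule, seed = 2)
  expect_true(is.finite(logJoint(i1$states, i1$params, d@counts,
                                 d@scenario@schedule)))
  expect_false(identical(i1$params, i2$params))
  # missing-month states lie between the log-linear interpolants
  dm <- d; sc <- d@scenario; sc@missingMonths <- 30L
  d2 <- simulateScenario(sc)
  i3 <- initializeChain(d2@counts, sc@schedule, seed = 3)
  lo <- pmin(log(d2@counts@y[29]), log(d2@counts@y[31]))
  hi <- pmax(log(d2@counts@y[29]), log(d2@counts@y[31]))
  expect_gte(log(i3$states@inCamp[30]), lo - 1e-9)
  expect_lte(log(i3$states@inCamp[30]), hi + 1e-9)
  expect_error(initializeChain(CountSeries(rep(NA_real_, 12))), "missing")
})

test_that("fit rejects degenerate data and is reproducible", {
  expect_error(fitSSM(CountSeries(rep(NA_real_, 30))), "missing")
  expect_error(fitSSM(CountSeries(c(100, 120, 90))), "24 months")
  d <- simulateScenario(defaultScenario(seed = 21))
  cfg <- McmcConfig(nChains = 2, nIter = 200, nBurnin = 100, seed = 5)
  f1 <- fitSSM(d@counts, d@scenario@schedule, cfg)
  f2 <- fitSSM(d@counts, d@scenario@schedule, cfg)
  expect_identical(f1@paramDraws, f2@paramDraws)
  expect_identical(f1@totalDraws, f2@totalDraws)
})

test_that("all draws stay inside the prior support", {
  d <- simulateScenario(defaultScenario(seed = 13))
  fit <- quickFit(d, nIter = 1000, nBurnin = 500, seed = 9)
  m <- paramMatrix(fit)
  expect_true(all(m[, "rho"] > 0 & m[, "rho"] < 0.11))
  expect_true(all(m[, "mu"] > 0 & m[, "mu"] < 0.1))
  expect_true(all(m[, "cMu"] > 1 & m[, "cMu"] < 10))
  expect_true(all(m[, "cRho"] > 0 & m[, "cRho"] < 1))
  expect_true(all(m[, "cR"] > 0 & m[, "cR"] < 1))
  expect_true(all(m[, "sigmaObs"] > 0.05 & m[, "sigmaObs"] < 0.47))
  expect_true(all(m[, "alpha1"] > 1))
  expect_true(all(m[, "alpha2"] > m[, "alpha1"] + 1))
  expect_true(all(rhat(fit) >= 1))
})

test_that("parameter-update acceptance rates settle in a sane band", {
  d <- simulateScenario(defaultScenario(seed = 17))
  fit <- quickFit(d, nIter = 2000, nBurnin = 1500, seed = 3)
  acc <- acceptanceRates(fit)[, c(roostSSM:::.PARAM_NAMES, "level")]
  expect_true(all(acc > 0.05 & acc < 0.7))
})

test_that("near-deterministic data pin down the recruitment rate", {
  # tiny noise everywhere: the monthly skeleton is almost exact, so the
  # posterior for rho must concentrate at its generative value
  sc <- defaultScenario(seed = 31)
  sc@schedule <- CycloneSchedule()
  sc@nMonths <- 300L
  sc@params@sigmaProc <- 0.005
  sc@params@sigmaCamp <- 0.005
  sc@params@sigmaObs <- 0.051
  d <- simulateScenario(sc)
  fit <- fitSSM(d@counts, CycloneSchedule(),
                McmcConfig(nChains = 2, nIter = 4000, nBurnin = 2000,
                           seed = 8))
  m <- paramMatrix(fit)
  expect_lt(abs(mean(m[, "rho"]) - 0.068), 0.005)
  expect_lt(abs(mean(m[, "mu"]) - 0.017), 0.005)
})

test_that("recruitment and mortality are positively associated a posteriori", {
  # the seasonal recruitment window partially identifies rho and mu
  # individually on synthetic data, so the joint posterior shows a
  # positive association rather than a degenerate ridge
  d <- simulateScenario(defaultScenario(seed = 23))
  fit <- quickFit(d, nIter = 3000, nBurnin = 1500, seed = 23, nChains = 3)
  m <- paramMatrix(fit)
  expect_gt(cor(m[, "rho"], m[, "mu"]), 0.1)
})

test_that("prior-only sampling needs no data beyond a stub and stays put", {
  d <- CountSeries(c(100, 120, 90, 110, 95, 105))
  fit <- fitSSM(d, config = McmcConfig(nChains = 2, nIter = 3000,
                                       nBurnin = 1000, seed = 2),
                priorOnly = TRUE)
  m <- paramMatrix(fit)
  # uniform prior marginals: compare mean and quantiles for a few blocks
  expect_lt(abs(mean(m[, "rho"]) - 0.055), 0.01)
  expect_lt(abs(mean(m[, "cMu"]) - 5.5), 0.4)
  expect_length(fit@stateIterations, 0)
})
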