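# Shared fixtures: the generative truth used across tests, a tiny
# hand-built dataset, and an independent term-by-term density oracle
# for the log joint.

truthParams <- function() {
  a2 <- 2 / (0.86 - 0.30)
  SsmParams(rho = 0.068, mu = 0.017, cRho = 0.79, cMu = 5.7, cR = 0.24,
            alpha1 = 0.86 * a2 - 1, alpha2 = a2,
            sigmaProc = 0.149, sigmaCamp = 0.15, sigmaObs = 0.096)
}

truthVector <- function() {
  p <- truthParams()
  c(rho = p@rho, mu = p@mu, cRho = p@cRho, cMu = p@cMu, cR = p@cR,
    alpha1 = p@alpha1, alpha2 = p@alpha2, sigmaProc = p@sigmaProc,
    sigmaCamp = p@sigmaCamp, sigmaObs = p@sigmaObs)
}

# five months starting in November (calendar 11, 12, 1, 2, 3), one
# cyclone at month 3, one missing month
tinyData <- function() {
  CountSeries(c(1000, 1500, NA, 1200, 700), startCalendarMonth = 11L)
}

tinySchedule <- function() CycloneSchedule(3L, rampLength = 12L)

tinyStates <- function() {
  LatentTrajectory(total = c(1800, 1900, 2000, 1850, 1700),
                   inCamp = c(1050, 1480, 1300, 1150, 720))
}

# Independent oracle: the log joint as an explicit sum of univariate
# log-normal log densities, with every per-month quantity written out
# longhand (explicit loop, literal formulas) rather than through the
# package's model functions.
oracleLogJoint <- function(states, params, data, schedule,
                           x0PriorSd = 0.5) {
  x <- states@total; xc <- states@inCamp
  y <- data@y; cm <- data@calendarMonth
  n <- length(y)
  a1 <- params@alpha1; a2 <- params@alpha2

  rampAt <- function(t) {
    r <- 0
    for (e in schedule@eventMonths) {
      if (t >= e && t < e + schedule@rampLength)
        r <- max(r, 1 - (t - e) / schedule@rampLength)
    }
    r
  }
  pAt <- function(t) {
    (cos(2 * pi * cm[t] / 12) + a1) / a2 * (1 - params@cR * rampAt(t))
  }
  # first December at or after an event marks the penalized season
  calAt <- function(t) ((cm[1] - 1 + t - 1) %% 12) + 1
  penalizedSeasonStarts <- vapply(schedule@eventMonths, function(e) {
    d <- e
    while (calAt(d) != 12) d <- d + 1
    d
  }, numeric(1))
  rhoAt <- function(t) {
    if (!(cm[t] %in% c(12, 1, 2))) return(0)
    seasonStart <- t - match(cm[t], c(12, 1, 2)) + 1
    f <- if (seasonStart %in% penalizedSeasonStarts) params@cRho else 1
    params@rho * f
  }
  muAt <- function(t) params@mu * (1 + (params@cMu - 1) * rampAt(t))

  lp <- logPrior(params)
  # initial state anchored at first count over nominal availability
  a2n <- 2 / (0.86 - 0.30); a1n <- 0.86 * a2n - 1
  t1 <- which(data@observed)[1]
  pNom <- (cos(2 * pi * cm[t1] / 12) + a1n) / a2n
  lp <- lp + dlnorm(x[1], log(y[t1] / pNom), x0PriorSd, log = TRUE)
  for (t in 2:n)
    lp <- lp + dlnorm(x[t], log(x[t - 1] * exp(rhoAt(t) - muAt(t))),
                      params@sigmaProc, log = TRUE)
  for (t in 1:n)
    lp <- lp + dlnorm(xc[t], log(pAt(t) * x[t]), params@sigmaCamp,
                      log = TRUE)
  for (t in 1:n)
    if (data@observed[t])
      lp <- lp + dlnorm(y[t], log(xc[t]), params@sigmaObs, log = TRUE)
  lp
}

# quick reduced-size fit used by several tests
quickFit <- function(d, nIter = 2000, nBurnin = 1000, seed = 1,
                     nChains = 2) {
  fitSSM(d@counts, d@scenario@schedule,
         McmcConfig(nChains = nChains, nIter = nIter, nBurnin = nBurnin,
                    seed = seed))
}
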