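## Expected per-event log-abundance decrement of one cyclone, from the
## deterministic monthly skeleton (recruitment Dec-Feb, mortality along
## the recovery ramp), averaged over the 12 possible placements of the
## event within the year. Returns the two structural constants the
## decrement is linear in: the summed ramp fraction (months of excess
## mortality weight) and the number of penalized breeding months.
.skeletonPhaseSums <- function(rampLength = 12L) {
  t <- 1:60
  rampSum <- numeric(12)
  penCount <- numeric(12)
  for (phase in 0:11) {
    sched <- CycloneSchedule(13L + phase, rampLength = rampLength)
    cm <- calendarMonthAt(t, 1L)
    rampSum[phase + 1] <- sum(cycloneRamp(t, sched))
    penCount[phase + 1] <- sum(.recruitmentPenalized(t, cm, sched) &
                                 cm %in% c(12L, 1L, 2L))
  }
  c(rampSum = mean(rampSum), penCount = mean(penCount))
}

#' Yearly exponential rate of increase from the deterministic skeleton
#'
#' Runs the noise-free monthly skeleton: recruitment \code{rho} over
#' December-February, mortality \code{mu} year-round, cyclones arriving
#' at \code{cycloneFrequency} events per year, each imposing the excess
#' mortality ramp and one penalized breeding season, with the event
#' placement averaged over the twelve months of the year. At frequency
#' zero this reduces exactly to \code{3 * rho - 12 * mu}.
#'
#' @param params an \code{\linkS4class{SsmParams}}
#' @param cycloneFrequency cyclone events per year (>= 0)
#' @param rampLength months to full recovery after an event
#' @return yearly exponential rate of increase (yr^-1)
#' @examples
#' skeletonRate(SsmParams(rho = 0.068, mu = 0.017), 0)        # exactly 0
#' skeletonRate(SsmParams(), 3 / (154 / 12))                  # ~ -0.13
#' @export
skeletonRate <- function(params, cycloneFrequency, rampLength = 12L) {
  stopifnot(is(params, "SsmParams"))
  if (cycloneFrequency < 0) stop("cyclone frequency must be non-negative")
  s <- .skeletonPhaseSums(rampLength)
  r0 <- 3 * params@rho - 12 * params@mu
  dec <- params@mu * (params@cMu - 1) * s[["rampSum"]] +
    params@rho * (1 - params@cRho) * s[["penCount"]]
  r0 - cycloneFrequency * dec
}

#' Posterior yearly rates of increase with and without cyclones
#'
#' For every posterior draw, computes the yearly exponential rate of
#' increase from the deterministic skeleton (see
#' \code{\link{skeletonRate}}) at cyclone frequency zero and at the
#' stated frequency, and the posterior probability of decline
#' \code{P(r < 0)} at that frequency. The default frequency is the
#' observed one: the number of scheduled events divided by the span of
#' the fitted series in years.
#'
#' @param draws a \code{\linkS4class{PosteriorDraws}} (or a numeric
#'   matrix of parameter draws with the model's column names)
#' @param cycloneFrequency events per year; \code{NULL} for the
#'   observed frequency of the fitted schedule
#' @param rampLength months to recovery
#' @return a \code{\linkS4class{DerivedRates}}
#' @export
rateOfIncrease <- function(draws, cycloneFrequency = NULL,
                           rampLength = 12L) {
  if (is(draws, "PosteriorDraws")) {
    if (is.null(cycloneFrequency))
      cycloneFrequency <- length(draws@schedule@eventMonths) /
        (length(draws@data@y) / 12)
    m <- paramMatrix(draws)
  } else {
    m <- as.matrix(draws)
    if (is.null(cycloneFrequency))
      stop("cycloneFrequency must be given for raw draw matrices")
  }
  if (nrow(m) == 0L) stop("no posterior draws")
  if (cycloneFrequency < 0) stop("cyclone frequency must be non-negative")
  s <- .skeletonPhaseSums(rampLength)
  r0 <- 3 * m[, "rho"] - 12 * m[, "mu"]
  dec <- m[, "mu"] * (m[, "cMu"] - 1) * s[["rampSum"]] +
    m[, "rho"] * (1 - m[, "cRho"]) * s[["penCount"]]
  rf <- r0 - cycloneFrequency * dec
  new("DerivedRates", rNoCyclone = unname(r0), rWithCyclone = unname(rf),
      cycloneFrequency = cycloneFrequency,
      pDecline = mean(rf < 0))
}

#' Posterior probability of decline
#'
#' Fraction of posterior draws with a negative yearly rate of increase.
#'
#' @param rates a \code{\linkS4class{DerivedRates}} (or numeric draws of r)
#' @param which rate at the stated cyclone frequency (default) or
#'   without cyclones
#' @return probability in [0, 1]
#' @export
probDecline <- function(rates, which = c("withCyclone", "noCyclone")) {
  which <- match.arg(which)
  r <- if (is(rates, "DerivedRates")) {
    if (which == "withCyclone") rates@rWithCyclone else rates@rNoCyclone
  } else as.numeric(rates)
  if (!length(r)) stop("no draws")
  mean(r < 0)
}

#' November posterior summaries of the latent populations
#'
#' Posterior medians and central 95\% intervals of the total and
#' in-camp populations for every November in the fitted series, with
#' the observed November count alongside.
#'
#' @param draws a \code{\linkS4class{PosteriorDraws}} with stored states
#' @param data the fitted series; defaults to the one in \code{draws}
#' @return data.frame with one row per November: month index, year
#'   ordinal, 2.5/50/97.5 percent quantiles of both states, observed count
#' @export
novemberSummary <- function(draws, data = NULL) {
  stopifnot(is(draws, "PosteriorDraws"))
  if (is.null(data)) data <- draws@data
  nov <- which(data@calendarMonth == 11L)
  if (!length(nov)) stop("the series contains no November months")
  total <- stateDraws(draws, "total")
  inCamp <- stateDraws(draws, "inCamp")
  if (!nrow(total)) stop("no stored state draws")
  q <- function(m) t(apply(m[, nov, drop = FALSE], 2L, quantile,
                           probs = c(0.025, 0.5, 0.975), names = FALSE))
  qt <- q(total); qc <- q(inCamp)
  data.frame(monthIndex = nov, year = seq_along(nov),
             totalLower = qt[, 1], totalMedian = qt[, 2],
             totalUpper = qt[, 3], inCampLower = qc[, 1],
             inCampMedian = qc[, 2], inCampUpper = qc[, 3],
             observed = data@y[nov])
}

#' Percent decline between two months of the series
#'
#' Per posterior draw, \code{100 * (1 - X_to / X_from)} for the latent
#' total population; the posterior median is returned.
#'
#' @param draws a \code{\linkS4class{PosteriorDraws}} with stored states
#' @param fromMonth,toMonth month indices on the series axis
#' @return median percent decline (negative for an increase)
#' @export
percentDecline <- function(draws, fromMonth, toMonth) {
  total <- stateDraws(draws, "total")
  if (!nrow(total)) stop("no stored state draws")
  median(100 * (1 - total[, toMonth] / total[, fromMonth]))
}

#' Project the population forward from a fit
#'
#' For each retained state draw (and its parameter draw), simulates the
#' process and in-camp layers forward for \code{horizonMonths} under a
#' stated future cyclone schedule (on the extended month axis), and
#' returns per-month posterior predictive quantiles for both states.
#' Horizon zero returns the quantiles of the last fitted state.
#'
#' @param draws a \code{\linkS4class{PosteriorDraws}} with stored states
#' @param horizonMonths months to project (>= 0)
#' @param futureSchedule cyclone schedule; event months may lie beyond
#'   the fitted series (past events still in their ramp also apply)
#' @param seed RNG seed for the projection noise
#' @return list with data.frames \code{total} and \code{inCamp}
#'   (columns monthIndex, lower, median, upper)
#' @export
projectPopulation <- function(draws, horizonMonths,
                              futureSchedule = NULL, seed = 1L) {
  stopifnot(is(draws, "PosteriorDraws"))
  if (horizonMonths < 0) stop("horizon must be non-negative")
  n <- length(draws@data@y)
  startCM <- draws@data@calendarMonth[1L]
  sched <- if (is.null(futureSchedule)) draws@schedule else {
    CycloneSchedule(sort(unique(c(draws@schedule@eventMonths,
                                  futureSchedule@eventMonths))),
                    rampLength = draws@schedule@rampLength,
                    useRamp = draws@schedule@useRamp)
  }
  ## pair each thinned state draw with its parameter draw
  par <- do.call(rbind, lapply(draws@paramDraws, function(m)
    m[draws@stateIterations, , drop = FALSE]))
  lx <- log(stateDraws(draws, "total"))
  lxc <- log(stateDraws(draws, "inCamp"))
  if (!nrow(lx)) stop("no stored state draws to project from")
  nd <- nrow(lx)
  set.seed(seed)
  curX <- lx[, n]
  months <- if (horizonMonths == 0L) n else n + seq_len(horizonMonths)
  qsX <- matrix(NA_real_, length(months), 3L)
  qsC <- matrix(NA_real_, length(months), 3L)
  if (horizonMonths == 0L) {
    qsX[1L, ] <- quantile(exp(curX), c(0.025, 0.5, 0.975), names = FALSE)
    qsC[1L, ] <- quantile(exp(lxc[, n]), c(0.025, 0.5, 0.975), names = FALSE)
  } else {
    for (h in seq_len(horizonMonths)) {
      tt <- n + h
      cm <- calendarMonthAt(tt, startCM)
      ramp <- cycloneRamp(tt, sched)
      pen <- .recruitmentPenalized(tt, cm, sched)
      breeding <- cm %in% c(12L, 1L, 2L)
      g <- par[, "rho"] * as.numeric(breeding) *
        ifelse(pen, par[, "cRho"], 1) -
        par[, "mu"] * (1 + (par[, "cMu"] - 1) * ramp)
      curX <- rnorm(nd, curX + g, par[, "sigmaProc"])
      logp <- log(cos(2 * pi * cm / 12) + par[, "alpha1"]) -
        log(par[, "alpha2"]) + log1p(-par[, "cR"] * ramp)
      curC <- rnorm(nd, logp + curX, par[, "sigmaCamp"])
      qsX[h, ] <- quantile(exp(curX), c(0.025, 0.5, 0.975), names = FALSE)
      qsC[h, ] <- quantile(exp(curC), c(0.025, 0.5, 0.975), names = FALSE)
    }
  }
  list(total = data.frame(monthIndex = months, lower = qsX[, 1],
                          median = qsX[, 2], upper = qsX[, 3]),
       inCamp = data.frame(monthIndex = months, lower = qsC[, 1],
                           median = qsC[, 2], upper = qsC[, 3]))
}
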