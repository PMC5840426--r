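#' Default simulation scenario
#'
#' A 154-month monitoring series starting in May, with three cyclone
#' impacts (month indices 23, 82 and 106, i.e. March of year 2, February
#' of years 7 and 9 on a May start), 64 known camps with 10.5 occupied
#' on average, and parameter values chosen to emulate a declining
#' flying-fox population: process SD 0.149, observation SD 0.096,
#' mortality 0.017/month with a 5.7-fold cyclone multiplier, recruitment
#' multiplier 0.79 in the first post-cyclone season, in-camp proportion
#' reduced by 24\% at impact, and seasonality solved so that 86\% of the
#' population is in camps in December and 30\% in June
#' (alpha2 = 2 / (0.86 - 0.30), alpha1 = 0.86 * alpha2 - 1).
#' Recruitment is set to rho = 4 * mu = 0.068 so the cyclone-free yearly
#' rate 3 * rho - 12 * mu is exactly zero. Initial population 326,000.
#'
#' @param seed RNG seed carried by the scenario
#' @return a \code{\linkS4class{Scenario}}
#' @examples
#' sc <- defaultScenario()
#' sc@schedule@eventMonths
#' @export
defaultScenario <- function(seed = 1L) {
  alpha2 <- 2 / (0.86 - 0.30)
  alpha1 <- 0.86 * alpha2 - 1
  Scenario(
    params = SsmParams(rho = 0.068, mu = 0.017, cRho = 0.79, cMu = 5.7,
                       cR = 0.24, alpha1 = alpha1, alpha2 = alpha2,
                       sigmaProc = 0.149, sigmaCamp = 0.15,
                       sigmaObs = 0.096),
    nMonths = 154L, startCalendarMonth = 5L, x0 = 326000,
    schedule = CycloneSchedule(c(23L, 82L, 106L)),
    nCamps = 64L, meanOccupied = 10.5, seed = seed)
}

#' Simulate a monitoring dataset from the generative model
#'
#' Draws the latent total population sequentially from the log-normal
#' process layer (starting at \code{x0} exactly), the in-camp population
#' from the seasonal-availability layer, and observed totals from the
#' observation layer; months listed in \code{missingMonths} keep their
#' latent states but have no observation. Optionally partitions each
#' observed total across a random set of occupied camps
#' (\code{perCamp = TRUE}) for I/O realism.
#'
#' @param scenario a \code{\linkS4class{Scenario}}
#' @param perCamp also build the camps x months per-camp count matrix
#' @return a \code{\linkS4class{SimulatedDataset}}
#' @examples
#' d <- simulateScenario(defaultScenario(seed = 42))
#' head(d@counts@y)
#' @export
simulateScenario <- function(scenario, perCamp = FALSE) {
  stopifnot(is(scenario, "Scenario"))
  validObject(scenario)
  set.seed(scenario@seed)
  n <- scenario@nMonths
  pr <- scenario@params
  t <- seq_len(n)
  cm <- calendarMonthAt(t, scenario@startCalendarMonth)
  ramp <- cycloneRamp(t, scenario@schedule)
  p <- .seasonalProportionAt(cm, ramp, pr)
  breeding <- cm %in% c(12L, 1L, 2L)
  pen <- .recruitmentPenalized(t, cm, scenario@schedule)
  rho_t <- pr@rho * as.numeric(breeding) * ifelse(pen, pr@cRho, 1)
  mu_t <- pr@mu * (1 + (pr@cMu - 1) * ramp)

  x <- numeric(n)
  x[1L] <- scenario@x0
  for (i in 2:n)
    x[i] <- rlnorm(1L, log(x[i - 1L]) + rho_t[i] - mu_t[i], pr@sigmaProc)
  xc <- rlnorm(n, log(p * x), pr@sigmaCamp)
  y <- rlnorm(n, log(xc), pr@sigmaObs)
  y[scenario@missingMonths] <- NA_real_
  if (scenario@roundCounts) y <- round(y)

  counts <- new("CountSeries", monthIndex = t, calendarMonth = cm,
                y = y, observed = !is.na(y), start = NA_character_)
  pc <- matrix(numeric(0), nrow = scenario@nCamps, ncol = 0)
  if (perCamp) {
    pc <- matrix(0, nrow = scenario@nCamps, ncol = n,
                 dimnames = list(sprintf("camp%02d", seq_len(scenario@nCamps)),
                                 NULL))
    for (i in which(!is.na(y)))
      pc[, i] <- splitToCamps(y[i], nCamps = scenario@nCamps,
                              occupancy = scenario@meanOccupied,
                              concentration = scenario@concentration)
  }
  new("SimulatedDataset", scenario = scenario, truthParams = pr,
      truthStates = LatentTrajectory(x, xc), counts = counts, perCamp = pc)
}

#' Partition a monthly total across occupied camps
#'
#' Draws the number of occupied camps as 1 + Binomial(nCamps - 1,
#' (occupancy - 1)/(nCamps - 1)) (so the expected count of occupied
#' camps equals \code{occupancy} and at least one camp holds the
#' animals), selects the occupied set uniformly, and splits the total
#' among them with symmetric Dirichlet weights. The split always sums
#' to the input total.
#'
#' @param total monthly total to partition (>= 0)
#' @param nCamps number of known camps
#' @param occupancy expected number of occupied camps
#' @param concentration symmetric Dirichlet concentration of the split
#' @param seed optional seed; when NULL the current RNG stream is used
#' @return numeric vector of length \code{nCamps} summing to \code{total}
#' @examples
#' sum(splitToCamps(1000, seed = 1))
#' @export
splitToCamps <- function(total, nCamps = 64L, occupancy = 10.5,
                         concentration = 5, seed = NULL) {
  if (total < 0) stop("total must be non-negative")
  if (occupancy > nCamps) stop("occupancy cannot exceed nCamps")
  if (!is.null(seed)) set.seed(seed)
  out <- numeric(nCamps)
  if (total == 0) return(out)
  k <- 1L + rbinom(1L, nCamps - 1L, (occupancy - 1) / (nCamps - 1))
  occ <- sample.int(nCamps, k)
  w <- rgamma(k, shape = concentration, rate = 1)
  out[occ] <- total * w / sum(w)
  out
}
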