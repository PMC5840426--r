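#' @useDynLib roostSSM, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
#' @importFrom stats dlnorm dbeta dunif runif rbeta rnorm rlnorm rbinom
#'   rgamma quantile ks.test approx cor median var sd dnorm setNames ave
#' @importFrom utils read.csv write.csv packageVersion
#' @importFrom graphics par
NULL

.PARAM_NAMES <- c("rho", "mu", "cRho", "cMu", "cR",
                  "alpha1", "alpha2", "sigmaProc", "sigmaCamp", "sigmaObs")

#' Model parameters for the roost-count state-space model
#'
#' Holds the ten scalar parameters of the hierarchical model: background
#' monthly recruitment (\code{rho}) and mortality (\code{mu}) rates, the
#' cyclone multipliers on recruitment (\code{cRho}, in (0,1)), mortality
#' (\code{cMu}, at least 1) and in-camp proportion (\code{cR}, in (0,1)),
#' the seasonality parameters \code{alpha1}, \code{alpha2} of the cosine
#' availability curve, and the three log-scale standard deviations:
#' process noise (\code{sigmaProc}), in-camp (roosting aggregation) noise
#' (\code{sigmaCamp}) and observation (counting) error (\code{sigmaObs}).
#'
#' Validity enforces structural constraints only (finite scalars,
#' non-negative rates, positive SDs, multipliers in their natural ranges);
#' the prior support of Table-style bounds is the business of
#' \code{\link{logPrior}}, which returns \code{-Inf} outside support so
#' that out-of-support values can still be represented and scored.
#'
#' @slot rho monthly recruitment rate (month^-1, applies December-February)
#' @slot mu monthly mortality rate (month^-1)
#' @slot cRho cyclone multiplier on the first post-cyclone breeding season
#' @slot cMu cyclone multiplier on mortality at impact
#' @slot cR cyclone reduction of the in-camp proportion at impact
#' @slot alpha1 seasonality offset (> 1 for a valid proportion curve)
#' @slot alpha2 seasonality scale (> alpha1 + 1)
#' @slot sigmaProc process SD on the log scale
#' @slot sigmaCamp in-camp process SD on the log scale
#' @slot sigmaObs observation SD on the log scale
#' @export
setClass("SsmParams",
  representation(rho = "numeric", mu = "numeric", cRho = "numeric",
                 cMu = "numeric", cR = "numeric", alpha1 = "numeric",
                 alpha2 = "numeric", sigmaProc = "numeric",
                 sigmaCamp = "numeric", sigmaObs = "numeric"))

setValidity("SsmParams", function(object) {
  v <- vapply(.PARAM_NAMES, function(s) slot(object, s), numeric(1))
  if (any(!is.finite(v)))
    return("all parameters must be finite scalars")
  if (object@rho < 0 || object@mu < 0)
    return("rho and mu must be non-negative")
  if (object@sigmaProc <= 0 || object@sigmaCamp <= 0 || object@sigmaObs <= 0)
    return("all standard deviations must be positive")
  if (object@cMu <= 0)
    return("cMu must be positive")
  if (object@cRho < 0 || object@cRho > 1 || object@cR < 0 || object@cR > 1)
    return("cRho and cR must lie in [0, 1]")
  TRUE
})

#' Construct an SsmParams object
#'
#' @param rho,mu,cRho,cMu,cR,alpha1,alpha2,sigmaProc,sigmaCamp,sigmaObs
#'   scalar parameters; see \code{\linkS4class{SsmParams}}.
#' @return an \code{SsmParams} object
#' @examples
#' SsmParams(rho = 0.068, mu = 0.017)
#' @export
SsmParams <- function(rho = 0.068, mu = 0.017, cRho = 0.79, cMu = 5.7,
                      cR = 0.24, alpha1 = 2.0714286, alpha2 = 3.5714286,
                      sigmaProc = 0.149, sigmaCamp = 0.15,
                      sigmaObs = 0.096) {
  new("SsmParams", rho = rho, mu = mu, cRho = cRho, cMu = cMu, cR = cR,
      alpha1 = alpha1, alpha2 = alpha2, sigmaProc = sigmaProc,
      sigmaCamp = sigmaCamp, sigmaObs = sigmaObs)
}

#' Cyclone disturbance schedule
#'
#' Event months are indices on the series' own month axis (1 = first
#' month). Each event imposes its full effect at impact and decays
#' linearly to zero over \code{rampLength} months; setting
#' \code{useRamp = FALSE} switches to a pure year-long indicator
#' (1 for the 12 months from impact, then 0).
#'
#' @slot eventMonths strictly increasing integer month indices
#' @slot rampLength months to full recovery (default 12)
#' @slot useRamp linear ramp (TRUE) or year indicator (FALSE)
#' @export
setClass("CycloneSchedule",
  representation(eventMonths = "integer", rampLength = "integer",
                 useRamp = "logical"))

setValidity("CycloneSchedule", function(object) {
  e <- object@eventMonths
  if (length(e) && any(diff(e) <= 0))
    return("eventMonths must be strictly increasing")
  if (length(object@rampLength) != 1L || object@rampLength < 1L)
    return("rampLength must be a single integer >= 1")
  TRUE
})

#' @rdname CycloneSchedule-class
#' @param eventMonths integer month indices of cyclone impacts
#' @param rampLength months to full recovery
#' @param useRamp use the linear recovery ramp (default) or a year indicator
#' @return a \code{CycloneSchedule}
#' @examples
#' CycloneSchedule(c(23, 82, 106))
#' @export
CycloneSchedule <- function(eventMonths = integer(0), rampLength = 12L,
                            useRamp = TRUE) {
  new("CycloneSchedule", eventMonths = as.integer(eventMonths),
      rampLength = as.integer(rampLength), useRamp = useRamp)
}

#' Monthly count series
#'
#' Observed monthly totals on a contiguous month axis. \code{y} is
#' \code{NA} exactly where \code{observed} is \code{FALSE}; a missing
#' survey month is distinct from a zero count.
#'
#' @slot monthIndex contiguous integer month axis starting at 1
#' @slot calendarMonth calendar month (1-12) of each index
#' @slot y observed total count per month (NA when unobserved)
#' @slot observed logical survey flag per month
#' @slot start optional "YYYY-MM" label of the first month
#' @export
setClass("CountSeries",
  representation(monthIndex = "integer", calendarMonth = "integer",
                 y = "numeric", observed = "logical", start = "character"))

setValidity("CountSeries", function(object) {
  n <- length(object@monthIndex)
  if (length(object@calendarMonth) != n || length(object@y) != n ||
      length(object@observed) != n)
    return("monthIndex, calendarMonth, y and observed must have equal length")
  if (n && any(diff(object@monthIndex) != 1L))
    return("monthIndex must be contiguous and increasing")
  if (n && !all(object@calendarMonth %in% 1:12))
    return("calendarMonth must be in 1..12")
  if (n > 1L) {
    step <- (object@calendarMonth[-1] - object@calendarMonth[-n]) %% 12L
    if (any(step != 1L))
      return("calendarMonth must advance by one month per index")
  }
  if (any(is.na(object@y) != !object@observed))
    return("y must be NA exactly on unobserved months")
  if (any(object@y[object@observed] < 0))
    return("counts must be non-negative")
  TRUE
})

#' @rdname CountSeries-class
#' @param y numeric monthly totals, NA for unsurveyed months
#' @param startCalendarMonth calendar month (1-12) of the first entry
#' @param start optional "YYYY-MM" label for the first entry
#' @return a \code{CountSeries}
#' @examples
#' CountSeries(c(100, NA, 140), startCalendarMonth = 5)
#' @export
CountSeries <- function(y, startCalendarMonth = 5L, start = NA_character_) {
  n <- length(y)
  idx <- seq_len(n)
  new("CountSeries", monthIndex = idx,
      calendarMonth = calendarMonthAt(idx, as.integer(startCalendarMonth)),
      y = as.numeric(y), observed = !is.na(y), start = start)
}

#' Latent population trajectory
#'
#' Monthly total population and in-camp population, both strictly
#' positive and of equal length.
#'
#' @slot total total population per month (animals)
#' @slot inCamp population roosting in known camps per month (animals)
#' @export
setClass("LatentTrajectory",
  representation(total = "numeric", inCamp = "numeric"))

setValidity("LatentTrajectory", function(object) {
  if (length(object@total) != length(object@inCamp))
    return("total and inCamp must have equal length")
  if (any(!is.finite(object@total)) || any(!is.finite(object@inCamp)))
    return("states must be finite")
  if (any(object@total <= 0) || any(object@inCamp <= 0))
    return("states must be strictly positive")
  TRUE
})

#' @rdname LatentTrajectory-class
#' @param total,inCamp positive numeric vectors of equal length
#' @return a \code{LatentTrajectory}
#' @export
LatentTrajectory <- function(total, inCamp) {
  new("LatentTrajectory", total = as.numeric(total),
      inCamp = as.numeric(inCamp))
}

#' Simulation scenario
#'
#' Bundles everything the generative simulator needs: the true
#' parameters, series dimensions, initial population, cyclone schedule,
#' camp structure for the per-camp presentation layer, explicit missing
#' months and the RNG seed.
#'
#' @slot params true \code{SsmParams}
#' @slot nMonths series length in months
#' @slot startCalendarMonth calendar month of month index 1
#' @slot x0 initial total population (animals)
#' @slot schedule cyclone schedule on the scenario's month axis
#' @slot nCamps number of known camps
#' @slot meanOccupied expected number of occupied camps per month
#' @slot concentration Dirichlet concentration of the per-camp split
#' @slot missingMonths month indices with no survey
#' @slot roundCounts round written counts to integers
#' @slot seed RNG seed
#' @export
setClass("Scenario",
  representation(params = "SsmParams", nMonths = "integer",
                 startCalendarMonth = "integer", x0 = "numeric",
                 schedule = "CycloneSchedule", nCamps = "integer",
                 meanOccupied = "numeric", concentration = "numeric",
                 missingMonths = "integer", roundCounts = "logical",
                 seed = "integer"))

setValidity("Scenario", function(object) {
  if (object@nMonths < 2L) return("nMonths must be at least 2")
  if (object@x0 <= 0) return("x0 must be positive")
  if (!(object@startCalendarMonth %in% 1:12))
    return("startCalendarMonth must be in 1..12")
  if (length(object@missingMonths) &&
      (any(object@missingMonths < 1L) ||
       any(object@missingMonths > object@nMonths)))
    return("missingMonths must lie on the time axis")
  if (object@meanOccupied > object@nCamps)
    return("meanOccupied cannot exceed nCamps")
  TRUE
})

#' @rdname Scenario-class
#' @param params true parameters
#' @param nMonths,startCalendarMonth,x0,schedule,nCamps,meanOccupied,concentration,missingMonths,roundCounts,seed
#'   see the class slots
#' @return a \code{Scenario}
#' @export
Scenario <- function(params = SsmParams(), nMonths = 154L,
                     startCalendarMonth = 5L, x0 = 326000,
                     schedule = CycloneSchedule(), nCamps = 64L,
                     meanOccupied = 10.5, concentration = 5,
                     missingMonths = integer(0), roundCounts = FALSE,
                     seed = 1L) {
  new("Scenario", params = params, nMonths = as.integer(nMonths),
      startCalendarMonth = as.integer(startCalendarMonth),
      x0 = as.numeric(x0), schedule = schedule,
      nCamps = as.integer(nCamps), meanOccupied = meanOccupied,
      concentration = concentration,
      missingMonths = as.integer(missingMonths),
      roundCounts = roundCounts, seed = as.integer(seed))
}

#' Simulated monitoring dataset
#'
#' @slot scenario the generating \code{Scenario}
#' @slot truthParams parameters used
#' @slot truthStates latent trajectory actually drawn
#' @slot counts observed monthly totals (with missing months)
#' @slot perCamp camps x months matrix partitioning each surveyed
#'   month's observed total across occupied camps (0 columns if not built)
#' @export
setClass("SimulatedDataset",
  representation(scenario = "Scenario", truthParams = "SsmParams",
                 truthStates = "LatentTrajectory", counts = "CountSeries",
                 perCamp = "matrix"))

#' MCMC configuration
#'
#' @slot nChains number of chains (>= 2 for diagnostics)
#' @slot nIter retained iterations per chain (post burn-in)
#' @slot nBurnin burn-in iterations (adaptation happens here only)
#' @slot thinStates thinning interval for stored latent states
#' @slot alphaMax truncation of the alpha1/alpha2 priors
#' @slot seed RNG seed (chain c uses seed + c)
#' @export
setClass("McmcConfig",
  representation(nChains = "integer", nIter = "integer",
                 nBurnin = "integer", thinStates = "integer",
                 alphaMax = "numeric", seed = "integer"))

setValidity("McmcConfig", function(object) {
  if (object@nIter < 1L) return("nIter must be positive")
  if (object@nChains < 1L) return("nChains must be positive")
  if (object@thinStates < 1L) return("thinStates must be >= 1")
  if (object@alphaMax <= 2) return("alphaMax must exceed 2")
  TRUE
})

#' @rdname McmcConfig-class
#' @param nChains,nIter,nBurnin,thinStates,alphaMax,seed see slots
#' @return an \code{McmcConfig}
#' @examples
#' McmcConfig(nIter = 5000, nBurnin = 2000, seed = 7)
#' @export
McmcConfig <- function(nChains = 3L, nIter = 50000L, nBurnin = 10000L,
                       thinStates = 10L, alphaMax = 50, seed = 1L) {
  new("McmcConfig", nChains = as.integer(nChains), nIter = as.integer(nIter),
      nBurnin = as.integer(nBurnin), thinStates = as.integer(thinStates),
      alphaMax = alphaMax, seed = as.integer(seed))
}

#' Posterior draws from a model fit
#'
#' Per-chain parameter draws (unthinned), thinned latent-state draws,
#' acceptance rates and Gelman-Rubin potential scale reduction factors.
#'
#' @slot paramDraws list (one matrix per chain, iterations x parameters)
#' @slot totalDraws list of matrices of log total population draws
#'   (thinned iterations x months); empty matrices in prior-only fits
#' @slot inCampDraws list of matrices of log in-camp population draws
#' @slot stateIterations iteration numbers at which states were stored
#' @slot acceptance list of named per-chain acceptance-rate vectors
#' @slot rhat named potential scale reduction factors per parameter
#' @slot config the \code{McmcConfig} used
#' @slot data the fitted \code{CountSeries}
#' @slot schedule the \code{CycloneSchedule} used
#' @export
setClass("PosteriorDraws",
  representation(paramDraws = "list", totalDraws = "list",
                 inCampDraws = "list", stateIterations = "integer",
                 acceptance = "list", rhat = "numeric",
                 config = "McmcConfig", data = "CountSeries",
                 schedule = "CycloneSchedule"))

#' Derived yearly rates of increase
#'
#' Per-draw yearly exponential rates of population increase with and
#' without cyclones, and the posterior probability of decline.
#'
#' @slot rNoCyclone yearly rate per draw at cyclone frequency 0 (3*rho - 12*mu)
#' @slot rWithCyclone yearly rate per draw at \code{cycloneFrequency}
#' @slot cycloneFrequency cyclone events per year used
#' @slot pDecline posterior probability that rWithCyclone < 0
#' @export
setClass("DerivedRates",
  representation(rNoCyclone = "numeric", rWithCyclone = "numeric",
                 cycloneFrequency = "numeric", pDecline = "numeric"))

#' Drift-diffusion-jump decomposition of a monitoring series
#'
#' @slot time month-axis grid at which estimates are evaluated
#' @slot conditionalVariance conditional variance of log increments
#' @slot totalVariance diffusion plus jump contribution
#' @slot diffusion diffusion component
#' @slot jumpIntensity jump intensity (events per month)
#' @slot bandwidth Gaussian kernel SD, in months
#' @slot nClamped number of negative moment-difference estimates clamped at 0
#' @export
setClass("DdjResult",
  representation(time = "numeric", conditionalVariance = "numeric",
                 totalVariance = "numeric", diffusion = "numeric",
                 jumpIntensity = "numeric", bandwidth = "numeric",
                 nClamped = "integer"))

setValidity("DdjResult", function(object) {
  n <- length(object@time)
  if (length(object@conditionalVariance) != n ||
      length(object@totalVariance) != n ||
      length(object@diffusion) != n ||
      length(object@jumpIntensity) != n)
    return("all estimate series must match the grid length")
  if (any(object@conditionalVariance < 0) || any(object@totalVariance < 0) ||
      any(object@diffusion < 0) || any(object@jumpIntensity < 0))
    return("variance and intensity estimates must be non-negative")
  TRUE
})
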