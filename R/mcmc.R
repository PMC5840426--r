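## precompute the per-month covariate series the sampler needs
.modelPrecomp <- function(data, schedule) {
  t <- data@monthIndex
  cm <- data@calendarMonth
  list(cosval = cos(2 * pi * cm / 12),
       ramp = cycloneRamp(t, schedule),
       breed = as.integer(cm %in% c(12L, 1L, 2L)),
       pen = as.integer(.recruitmentPenalized(t, cm, schedule)))
}

.paramsToVector <- function(params)
  vapply(.PARAM_NAMES, function(s) slot(params, s), numeric(1))

.vectorToParams <- function(v) {
  names(v) <- .PARAM_NAMES
  do.call(SsmParams, as.list(v))
}

#' Draw overdispersed initial values for one chain
#'
#' Parameters are drawn from their priors (independently per chain, so
#' chains start overdispersed); latent in-camp states are initialized at
#' the observed counts with log-linear interpolation across missing
#' months, and latent totals at those values divided by the seasonal
#' proportion implied by the drawn parameters. Redraws until the log
#' joint is finite (a bounded number of attempts).
#'
#' @param data a \code{\linkS4class{CountSeries}}
#' @param schedule a \code{\linkS4class{CycloneSchedule}}
#' @param seed RNG seed
#' @param alphaMax alpha-prior truncation
#' @param maxTries attempts before giving up
#' @param x0PriorSd log-scale SD of the initial-state prior
#' @return list with elements \code{params} (\code{SsmParams}) and
#'   \code{states} (\code{LatentTrajectory})
#' @export
initializeChain <- function(data, schedule = CycloneSchedule(), seed = 1L,
                            alphaMax = 50, maxTries = 100L,
                            x0PriorSd = 0.5) {
  stopifnot(is(data, "CountSeries"))
  if (!any(data@observed)) stop("all months are missing; cannot initialize")
  set.seed(seed)
  n <- length(data@y)
  obsIdx <- which(data@observed)
  ly <- approx(obsIdx, log(data@y[obsIdx]), xout = seq_len(n),
               rule = 2)$y
  for (i in seq_len(maxTries)) {
    a1 <- runif(1, 1.001, alphaMax)
    params <- SsmParams(
      rho = runif(1, 0, 0.11), mu = runif(1, 0, 0.1),
      cRho = rbeta(1, 1.01, 1.01), cMu = runif(1, 1, 10),
      cR = rbeta(1, 1.01, 1.01), alpha1 = a1,
      alpha2 = runif(1, a1 + 1.001, alphaMax + 1),
      sigmaProc = runif(1, 0, 10),
      sigmaCamp = runif(1, 0, 100), sigmaObs = runif(1, 0.05, 0.47))
    p <- seasonalProportion(data@monthIndex, params, schedule,
                            startCalendarMonth = data@calendarMonth[1L])
    states <- LatentTrajectory(exp(ly - log(p)), exp(ly))
    lj <- logJoint(states, params, data, schedule, alphaMax = alphaMax,
                   x0PriorSd = x0PriorSd)
    if (is.finite(lj)) return(list(params = params, states = states))
  }
  stop("could not find a finite starting point after ", maxTries, " attempts")
}

#' Fit the state-space model by MCMC
#'
#' Adaptive Metropolis-within-Gibbs targeting the full posterior:
#' single-parameter random walks on interval-logit transformed scales
#' (the seasonality pair is sampled as the December proportion and the
#' June/December ratio), evaluated against the collapsed likelihood
#' with the in-camp layer integrated out; a joint level move along the
#' near-flat availability/abundance scale direction; an exact Gibbs
#' draw of the log total-population path from its tridiagonal Gaussian
#' full conditional; and exact conjugate refreshes of the log in-camp
#' states. Proposal scales adapt during burn-in only. Runs
#' \code{nChains} chains from overdispersed prior starting points and
#' reports acceptance rates (exact draws count as 1) and Gelman-Rubin
#' potential scale reduction factors.
#'
#' With \code{priorOnly = TRUE} the sampler targets the prior alone
#' (no data terms, no state updates); this validates the parameter
#' kernel by comparison with the known prior marginals.
#'
#' @param data a \code{\linkS4class{CountSeries}} with at least 24
#'   months (unless \code{priorOnly})
#' @param schedule a \code{\linkS4class{CycloneSchedule}}
#' @param config an \code{\linkS4class{McmcConfig}}
#' @param priorOnly sample the prior instead of the posterior
#' @param x0PriorSd log-scale SD of the initial-state prior (see
#'   \code{\link{logJoint}})
#' @return a \code{\linkS4class{PosteriorDraws}}
#' @examples
#' d <- simulateScenario(defaultScenario(seed = 3))
#' \donttest{
#' fit <- fitSSM(d@counts, d@scenario@schedule,
#'               McmcConfig(nIter = 2000, nBurnin = 1000, seed = 3))
#' rhat(fit)
#' }
#' @export
fitSSM <- function(data, schedule = CycloneSchedule(),
                   config = McmcConfig(), priorOnly = FALSE,
                   x0PriorSd = 0.5) {
  stopifnot(is(data, "CountSeries"), is(config, "McmcConfig"))
  validObject(config)
  if (!any(data@observed)) stop("all months are missing; nothing to fit")
  if (!priorOnly && length(data@y) < 24L)
    stop("need at least 24 months of data")
  pre <- .modelPrecomp(data, schedule)
  logy <- ifelse(data@observed, log(data@y), 0)
  x0Mean <- .x0PriorMean(data)

  paramDraws <- vector("list", config@nChains)
  totalDraws <- vector("list", config@nChains)
  inCampDraws <- vector("list", config@nChains)
  acceptance <- vector("list", config@nChains)
  for (ch in seq_len(config@nChains)) {
    init <- initializeChain(data, schedule, seed = config@seed + ch,
                            alphaMax = config@alphaMax,
                            x0PriorSd = x0PriorSd)
    res <- .runChain(.paramsToVector(init$params),
                     log(init$states@total), log(init$states@inCamp),
                     logy, as.integer(data@observed), pre$cosval,
                     pre$ramp, pre$breed, pre$pen, x0Mean, x0PriorSd,
                     config@nIter, config@nBurnin, config@thinStates,
                     config@alphaMax, priorOnly)
    colnames(res$params) <- .PARAM_NAMES
    paramDraws[[ch]] <- res$params
    totalDraws[[ch]] <- res$logX
    inCampDraws[[ch]] <- res$logXC
    acceptance[[ch]] <- c(setNames(res$accParams, .PARAM_NAMES),
                          X = res$accX, XC = res$accXC,
                          level = res$accLevel)
  }
  rh <- if (config@nChains >= 2L) gelmanRubin(paramDraws)
        else setNames(rep(NA_real_, length(.PARAM_NAMES)), .PARAM_NAMES)
  stateIter <- if (priorOnly) integer(0)
               else as.integer(seq(config@thinStates, config@nIter,
                                   by = config@thinStates))
  new("PosteriorDraws", paramDraws = paramDraws, totalDraws = totalDraws,
      inCampDraws = inCampDraws, stateIterations = stateIter,
      acceptance = acceptance, rhat = rh, config = config, data = data,
      schedule = schedule)
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Classic between/within-chain variance diagnostic: for each parameter,
#' \code{sqrt(((n - 1)/n + B/(n W)))} where \code{W} is the mean
#' within-chain variance and \code{B} the between-chain variance of
#' chain means (times n). Values near 1 indicate convergence; reported
#' values are floored at 1 (the (n-1)/n finite-sample factor can push
#' the raw ratio fractionally below 1 when chains agree).
#'
#' @param chains a list of at least two equal-sized draw matrices
#'   (iterations x parameters), or a \code{PosteriorDraws} object
#' @return named numeric vector of PSRFs, one per parameter
#' @examples
#' set.seed(1)
#' a <- matrix(rnorm(200), ncol = 2); b <- matrix(rnorm(200), ncol = 2)
#' gelmanRubin(list(a, b))
#' @export
gelmanRubin <- function(chains) {
  if (is(chains, "PosteriorDraws")) chains <- chains@paramDraws
  if (!is.list(chains) || length(chains) < 2L)
    stop("need at least two chains for the Gelman-Rubin diagnostic")
  chains <- lapply(chains, as.matrix)
  n <- nrow(chains[[1L]])
  if (n < 10L) stop("chains must have at least 10 draws")
  if (any(vapply(chains, nrow, 1L) != n))
    stop("chains must have equal length")
  p <- ncol(chains[[1L]])
  out <- numeric(p)
  for (j in seq_len(p)) {
    draws <- vapply(chains, function(m) m[, j], numeric(n))
    W <- mean(apply(draws, 2L, var))
    B <- n * var(colMeans(draws))
    out[j] <- if (W == 0) {
      if (B == 0) 1 else Inf
    } else {
      max(1, sqrt((n - 1) / n + B / (n * W)))
    }
  }
  names(out) <- colnames(chains[[1L]])
  out
}

#' @describeIn fitSSM Pooled parameter draws across chains
#' @param draws a \code{PosteriorDraws}
#' @export
paramMatrix <- function(draws) {
  stopifnot(is(draws, "PosteriorDraws"))
  do.call(rbind, draws@paramDraws)
}

#' Potential scale reduction factors of a fit
#' @param draws a \code{PosteriorDraws}
#' @return named numeric vector
#' @export
rhat <- function(draws) {
  stopifnot(is(draws, "PosteriorDraws"))
  draws@rhat
}

#' Acceptance rates of a fit
#' @param draws a \code{PosteriorDraws}
#' @return matrix (chains x update types)
#' @export
acceptanceRates <- function(draws) {
  stopifnot(is(draws, "PosteriorDraws"))
  do.call(rbind, draws@acceptance)
}

#' Posterior draws of the latent states, pooled across chains
#'
#' @param draws a \code{PosteriorDraws}
#' @param which \code{"total"} or \code{"inCamp"}
#' @return matrix (retained draws x months) on the natural (animals) scale
#' @export
stateDraws <- function(draws, which = c("total", "inCamp")) {
  stopifnot(is(draws, "PosteriorDraws"))
  which <- match.arg(which)
  m <- if (which == "total") draws@totalDraws else draws@inCampDraws
  exp(do.call(rbind, m))
}
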