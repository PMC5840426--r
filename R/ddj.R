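#' Nonparametric drift-diffusion-jump decomposition of a count series
#'
#' Models the log-transformed monthly totals as a jump-diffusion and
#' estimates, as a function of time, the conditional variance of the
#' log increments, the diffusion component, the jump intensity and the
#' total variance (diffusion plus jump contribution). Conditional
#' moments of the increments are estimated by Gaussian-kernel (Nadaraya-
#' Watson) regression on time; jumps are separated from diffusion
#' through the excess fourth moment (excess kurtosis) of the
#' increments, with the squared jump size estimated from the excess
#' sixth moment. For a pure Gaussian random walk all excess moments
#' vanish, so the jump intensity is near zero and the total variance
#' equals the increment variance; isolated large shocks concentrate the
#' fourth-moment excess at their location, producing local maxima of
#' the jump intensity there.
#'
#' Missing months (at most 10\% of the series) are interpolated
#' log-linearly before differencing. Negative moment-difference
#' estimates are clamped at zero and counted in \code{nClamped}.
#'
#' @param series a \code{\linkS4class{CountSeries}} (length >= 24,
#'   >= 90\% observed) or a numeric vector of monthly totals
#' @param bandwidth Gaussian kernel SD in months (> 0)
#' @param gridSize number of evaluation points spanning the time axis;
#'   defaults to one per increment
#' @param deseasonalize subtract calendar-month means of the log series
#'   before differencing (only available for \code{CountSeries} input)
#' @return a \code{\linkS4class{DdjResult}}
#' @examples
#' d <- simulateScenario(defaultScenario(seed = 9))
#' res <- ddj(d@counts)
#' which.max(res@jumpIntensity)
#' @export
ddj <- function(series, bandwidth = 3, gridSize = NULL,
                deseasonalize = FALSE) {
  if (bandwidth <= 0) stop("bandwidth must be positive")
  if (is(series, "CountSeries")) {
    y <- series@y
    if (length(y) < 24L) stop("series too short: need at least 24 months")
    if (mean(series@observed) < 0.9)
      stop("more than 10% of months are missing")
    if (any(!series@observed)) {
      obsIdx <- which(series@observed)
      y <- exp(approx(obsIdx, log(.offsetLog(y[obsIdx])), # nolint
                      xout = seq_along(y), rule = 2)$y)
    }
    x <- log(.offsetLog(y))
    if (deseasonalize) {
      cm <- series@calendarMonth
      x <- x - ave(x, cm)
    }
  } else {
    y <- as.numeric(series)
    if (length(y) < 24L) stop("series too short: need at least 24 months")
    if (any(is.na(y))) stop("numeric input must have no missing values")
    if (deseasonalize) stop("deseasonalize requires a CountSeries")
    x <- log(.offsetLog(y))
  }
  n <- length(x)
  dx <- diff(x)
  tm <- seq_len(n - 1L)  # increment between month t and t+1, indexed at t
  if (is.null(gridSize)) gridSize <- n - 1L
  grid <- seq(1, n - 1L, length.out = gridSize)

  ## drift-corrected residuals: each increment is centred by the
  ## leave-one-out kernel mean at its own time, so an isolated shock
  ## cannot absorb itself into the local drift estimate (which would
  ## split its jump signature into twin flanking peaks)
  K <- outer(tm, tm, function(a, b) dnorm((a - b) / bandwidth))
  diag(K) <- 0
  m1loo <- as.numeric(K %*% dx) / rowSums(K)
  r <- dx - m1loo

  ## jump-robust local diffusion scale: kernel-weighted median of |r|
  ## (rescaled to the Gaussian SD), computed once at the increment
  ## times and interpolated linearly in between -- a single jump barely
  ## moves the median, so the Gaussian reference moments
  ## 3 sigma^4 / 15 sigma^6 are not inflated at jump locations, while
  ## interpolation keeps the scale continuous along any output grid.
  Wref <- outer(tm, tm, function(a, b) dnorm((a - b) / bandwidth))
  Wref <- Wref / rowSums(Wref)
  sigDref <- vapply(seq_along(tm), function(i)
    .weightedMedian(abs(r), Wref[i, ]) / 0.6744898, numeric(1))

  ## conditional central moments against the robust scale
  moments <- function(at) {
    W <- outer(at, tm, function(a, b) dnorm((a - b) / bandwidth))
    W <- W / rowSums(W)
    sigD <- approx(tm, sigDref, xout = at, rule = 2)$y
    list(C2 = as.numeric(W %*% r^2),
         ex4 = as.numeric(W %*% r^4) - 3 * sigD^4,   # ~0 for Gaussian
         ex6 = as.numeric(W %*% r^6) - 15 * sigD^6)
  }

  ## global squared jump size from the ratio of excess moments at the
  ## data's own increment times (so the diffusion/jump split does not
  ## depend on the output grid); jump-dominated limit: ex6/ex4 = 5 sJ2
  ref <- moments(tm)
  e4 <- pmax(ref$ex4, 0); e6 <- pmax(ref$ex6, 0)
  sJ2 <- if (sum(e4) > 0) sum(e6) / (5 * sum(e4)) else 0

  m <- moments(grid)
  C2 <- pmax(m$C2, 0)
  nClamped <- sum(m$ex4 < 0) + sum(m$ex6 < 0)
  ex4 <- pmax(m$ex4, 0)
  lambda <- if (sJ2 > 0) ex4 / (3 * sJ2^2) else rep(0, gridSize)
  jumpVar <- lambda * sJ2
  nClamped <- nClamped + sum(C2 - jumpVar < 0)
  diffusion <- pmax(C2 - jumpVar, 0)
  total <- diffusion + jumpVar

  new("DdjResult", time = grid, conditionalVariance = C2,
      totalVariance = total, diffusion = diffusion,
      jumpIntensity = lambda, bandwidth = bandwidth,
      nClamped = as.integer(nClamped))
}

## half-minimum offset applied only when zeros occur
.offsetLog <- function(y) {
  if (any(y == 0)) y + min(y[y > 0]) / 2 else y
}

.weightedMedian <- function(x, w) {
  o <- order(x)
  cw <- cumsum(w[o]) / sum(w)
  x[o][which(cw >= 0.5)[1L]]
}


#' Locate the largest local maxima of the jump intensity
#'
#' @param result a \code{\linkS4class{DdjResult}}
#' @param k number of peaks to return
#' @return month positions of the k largest local maxima, in
#'   decreasing order of intensity
#' @export
jumpPeaks <- function(result, k = 3L) {
  stopifnot(is(result, "DdjResult"))
  z <- result@jumpIntensity
  n <- length(z)
  isMax <- vapply(seq_len(n), function(i) {
    left <- if (i > 1L) z[i - 1L] else -Inf
    right <- if (i < n) z[i + 1L] else -Inf
    z[i] > left && z[i] >= right && z[i] > 0
  }, logical(1))
  idx <- which(isMax)
  idx <- idx[order(z[idx], decreasing = TRUE)]
  result@time[utils::head(idx, k)]
}
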