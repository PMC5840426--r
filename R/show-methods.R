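setMethod("show", "SsmParams", function(object) {
  v <- vapply(.PARAM_NAMES, function(s) slot(object, s), numeric(1))
  cat("SsmParams:\n")
  print(round(v, 4))
})

setMethod("show", "CycloneSchedule", function(object) {
  cat("CycloneSchedule:",
      if (length(object@eventMonths))
        paste(object@eventMonths, collapse = ", ") else "no events",
      sprintf("(%s, %d-month recovery)\n",
              if (object@useRamp) "linear ramp" else "year indicator",
              object@rampLength))
})

setMethod("show", "CountSeries", function(object) {
  n <- length(object@y)
  cat(sprintf(
    "CountSeries: %d months (%d observed)%s\n", n, sum(object@observed),
    if (!is.na(object@start)) paste0(", starting ", object@start) else ""))
  if (any(object@observed))
    cat(sprintf("  observed totals: median %.0f, range %.0f-%.0f\n",
                median(object@y, na.rm = TRUE),
                min(object@y, na.rm = TRUE), max(object@y, na.rm = TRUE)))
})

setMethod("show", "Scenario", function(object) {
  cat(sprintf(
    "Scenario: %d months from calendar month %d, x0 = %.0f, %d cyclones, seed %d\n",
    object@nMonths, object@startCalendarMonth, object@x0,
    length(object@schedule@eventMonths), object@seed))
})

setMethod("show", "SimulatedDataset", function(object) {
  cat("SimulatedDataset\n  ")
  show(object@counts)
  if (ncol(object@perCamp))
    cat(sprintf("  per-camp table: %d camps x %d months\n",
                nrow(object@perCamp), ncol(object@perCamp)))
})

setMethod("show", "PosteriorDraws", function(object) {
  nc <- length(object@paramDraws)
  ni <- if (nc) nrow(object@paramDraws[[1L]]) else 0L
  cat(sprintf("PosteriorDraws: %d chains x %d iterations\n", nc, ni))
  if (length(object@rhat) && all(is.finite(object@rhat)))
    cat(sprintf("  max Rhat: %.3f\n", max(object@rhat)))
  if (length(object@stateIterations))
    cat(sprintf("  latent states stored at %d iterations per chain\n",
                length(object@stateIterations)))
})

setMethod("show", "DerivedRates", function(object) {
  cat(sprintf(
    paste0("DerivedRates (%d draws): r = %.3f/yr without cyclones, ",
           "%.3f/yr at %.3f events/yr; P(r < 0) = %.2f\n"),
    length(object@rWithCyclone), mean(object@rNoCyclone),
    mean(object@rWithCyclone), object@cycloneFrequency, object@pDecline))
})

setMethod("show", "DdjResult", function(object) {
  cat(sprintf(
    "DdjResult: %d grid points, bandwidth %.2f months, %d clamped estimates\n",
    length(object@time), object@bandwidth, object@nClamped))
})

#' Plot a drift-diffusion-jump decomposition
#'
#' Four panels against time: conditional variance, total variance,
#' diffusion and jump intensity.
#'
#' @param x a \code{\linkS4class{DdjResult}}
#' @param y ignored
#' @param ... passed to \code{plot.default}
#' @export
setMethod("plot", signature(x = "DdjResult", y = "missing"),
  function(x, y, ...) {
    old <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
    on.exit(graphics::par(old))
    panels <- list(`conditional variance` = x@conditionalVariance,
                   `total variance` = x@totalVariance,
                   diffusion = x@diffusion,
                   `jump intensity` = x@jumpIntensity)
    for (nm in names(panels))
      plot(x@time, panels[[nm]], type = "l", xlab = "month",
           ylab = nm, ...)
    invisible(NULL)
  })

#' Plot a monthly count series
#'
#' @param x a \code{\linkS4class{CountSeries}}
#' @param y ignored
#' @param ... passed to \code{plot.default}
#' @export
setMethod("plot", signature(x = "CountSeries", y = "missing"),
  function(x, y, ...) {
    plot(x@monthIndex, x@y, type = "o", pch = 16, cex = 0.6,
         xlab = "month", ylab = "observed total", ...)
    invisible(NULL)
  })
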