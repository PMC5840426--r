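## year-month arithmetic on "YYYY-MM" labels
.parseYearMonth <- function(x) {
  m <- regmatches(x, regexec("^([0-9]{4})-([0-9]{2})(-[0-9]{2})?$",
                             as.character(x)))
  bad <- vapply(m, length, 1L) == 0L
  if (any(bad))
    stop("unparseable date(s): ", paste(unique(x[bad]), collapse = ", "))
  yr <- as.integer(vapply(m, `[`, "", 2L))
  mo <- as.integer(vapply(m, `[`, "", 3L))
  if (any(mo < 1L | mo > 12L))
    stop("month out of range in date(s)")
  yr * 12L + (mo - 1L)  # absolute month number
}

.formatYearMonth <- function(absMonth) {
  sprintf("%04d-%02d", absMonth %/% 12L, absMonth %% 12L + 1L)
}

#' Read a per-camp count table into a monthly count series
#'
#' The table is comma-separated with a header and columns \code{date}
#' (ISO year-month, day optional), \code{camp_id}, \code{count}, and
#' optionally \code{method} and \code{surveyed}. Rows are aggregated to
#' monthly totals on a contiguous month axis spanning the table's date
#' range; a month with no surveyed rows is marked missing (not zero).
#' Duplicate camp-month rows and negative counts are rejected.
#'
#' @param path file path (or a data.frame already in the table layout)
#' @return a \code{\linkS4class{CountSeries}}
#' @export
readCounts <- function(path) {
  df <- if (is.data.frame(path)) path else read.csv(path,
                                                    stringsAsFactors = FALSE)
  need <- c("date", "camp_id", "count")
  if (!all(need %in% names(df)))
    stop("count table must have columns: ", paste(need, collapse = ", "))
  if (!nrow(df)) stop("empty count table")
  surveyed <- if ("surveyed" %in% names(df)) {
    as.logical(df$surveyed)
  } else rep(TRUE, nrow(df))
  surveyed[is.na(surveyed)] <- TRUE
  am <- .parseYearMonth(df$date)
  key <- paste(am, df$camp_id)
  if (anyDuplicated(key[surveyed]))
    stop("duplicate camp-month rows: ",
         paste(unique(key[surveyed][duplicated(key[surveyed])]),
               collapse = "; "))
  cnt <- as.numeric(df$count)
  if (any(surveyed & (is.na(cnt) | cnt < 0))) {
    warning("negative or missing counts on surveyed rows")
    stop("counts must be non-negative numbers")
  }
  axis <- seq(min(am), max(am))
  y <- rep(NA_real_, length(axis))
  tot <- tapply(cnt[surveyed], am[surveyed], sum)
  y[match(as.integer(names(tot)), axis)] <- as.numeric(tot)
  new("CountSeries", monthIndex = seq_along(axis),
      calendarMonth = as.integer(axis %% 12L + 1L),
      y = y, observed = !is.na(y), start = .formatYearMonth(axis[1L]))
}

#' Write a dataset as a per-camp count table
#'
#' Writes the comma-separated camp-count dialect read by
#' \code{\link{readCounts}}. For a \code{SimulatedDataset} with a
#' per-camp matrix, one row per occupied camp-month is written;
#' otherwise the monthly totals are written under a single pseudo-camp.
#' Missing survey months are encoded by row absence.
#'
#' @param x a \code{\linkS4class{SimulatedDataset}} or
#'   \code{\linkS4class{CountSeries}}
#' @param path output file
#' @param startDate "YYYY-MM" of month index 1; defaults to the series'
#'   own start label, or 2004 alignment when absent
#' @return the path, invisibly
#' @export
writeCounts <- function(x, path, startDate = NULL) {
  counts <- if (is(x, "SimulatedDataset")) x@counts else x
  stopifnot(is(counts, "CountSeries"))
  if (is.null(startDate)) {
    startDate <- if (!is.na(counts@start)) counts@start else
      sprintf("2004-%02d", counts@calendarMonth[1L])
  }
  am0 <- .parseYearMonth(startDate)
  dates <- .formatYearMonth(am0 + counts@monthIndex - 1L)
  pc <- if (is(x, "SimulatedDataset")) x@perCamp else
    matrix(numeric(0), 0, 0)
  rows <- list()
  for (i in which(counts@observed)) {
    if (ncol(pc)) {
      occ <- which(pc[, i] > 0)
      rows[[length(rows) + 1L]] <- data.frame(
        date = dates[i], camp_id = rownames(pc)[occ],
        count = pc[occ, i], stringsAsFactors = FALSE)
    } else {
      rows[[length(rows) + 1L]] <- data.frame(
        date = dates[i], camp_id = "all_camps", count = counts@y[i],
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write and read posterior parameter draws
#'
#' Columnar comma-separated layout: one row per retained iteration,
#' with chain and iteration columns followed by one column per
#' parameter.
#'
#' @param draws a \code{\linkS4class{PosteriorDraws}}
#' @param path file path
#' @return \code{writeDraws}: the path, invisibly. \code{readDraws}: a
#'   list of per-chain draw matrices.
#' @export
writeDraws <- function(draws, path) {
  stopifnot(is(draws, "PosteriorDraws"))
  tabs <- lapply(seq_along(draws@paramDraws), function(ch)
    data.frame(chain = ch, iteration = seq_len(nrow(draws@paramDraws[[ch]])),
               draws@paramDraws[[ch]]))
  write.csv(do.call(rbind, tabs), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeDraws
#' @export
readDraws <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  lapply(split(df, df$chain), function(d)
    as.matrix(d[, setdiff(names(d), c("chain", "iteration")), drop = FALSE]))
}

## write latent-state draw matrices (months as columns)
.writeStates <- function(draws, pathTotal, pathInCamp) {
  write.csv(stateDraws(draws, "total"), pathTotal, row.names = FALSE,
            quote = FALSE)
  write.csv(stateDraws(draws, "inCamp"), pathInCamp, row.names = FALSE,
            quote = FALSE)
}

#' Run an analysis stage end-to-end
#'
#' Executes one of the pipeline stages \code{simulate}, \code{fit},
#' \code{summarize}, \code{ddj} or \code{project} from a configuration
#' list (or the path of a YAML file with the same structure), writing
#' its artifacts and a run log (seed, configuration hash, versions)
#' into \code{outDir}. Configuration problems are reported
#' exhaustively before any work is done.
#'
#' Recognized keys (per command, besides \code{seed} and \code{outDir}):
#' \describe{
#'   \item{simulate}{\code{nMonths}, \code{x0}, \code{cycloneMonths},
#'     \code{missingMonths}, \code{startCalendarMonth}, \code{perCamp}}
#'   \item{fit}{\code{data} (counts csv), \code{cycloneMonths},
#'     \code{chains}, \code{iter}, \code{burnin}, \code{thin}}
#'   \item{summarize}{\code{draws} (draws csv), \code{cycloneFrequency}}
#'   \item{ddj}{\code{data}, \code{bandwidth}, \code{deseasonalize}}
#'   \item{project}{\code{fitDir} (a fit stage's outDir), \code{data},
#'     \code{horizon}, \code{futureCycloneMonths}}
#' }
#'
#' @param command stage name
#' @param config named list or YAML file path
#' @return invisibly, a list of the artifact paths written
#' @export
runCommand <- function(command, config) {
  commands <- c("simulate", "fit", "summarize", "ddj", "project")
  if (!command %in% commands)
    stop("unknown command '", command, "'; expected one of: ",
         paste(commands, collapse = ", "))
  configHash <- NA_character_
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    configHash <- unname(tools::md5sum(config))
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or a YAML file path")

  problems <- character(0)
  needsSeed <- command %in% c("simulate", "fit", "project")
  if (needsSeed && is.null(config$seed))
    problems <- c(problems, "seed is mandatory for stochastic commands")
  if (is.null(config$outDir))
    problems <- c(problems, "outDir is required")
  for (k in switch(command, fit = "data", ddj = "data",
                   summarize = "draws", project = c("fitDir", "data"),
                   character(0))) {
    if (is.null(config[[k]]))
      problems <- c(problems, paste0(k, " is required for ", command))
    else if (k != "fitDir" && !file.exists(config[[k]]))
      problems <- c(problems, paste0(k, " path does not exist: ",
                                     config[[k]]))
  }
  if (length(problems))
    stop("invalid configuration:\n  - ",
         paste(problems, collapse = "\n  - "))

  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  outfile <- function(f) file.path(config$outDir, f)
  artifacts <- character(0)
  seed <- if (!is.null(config$seed)) as.integer(config$seed) else NA_integer_

  if (command == "simulate") {
    sc <- defaultScenario(seed = seed)
    if (!is.null(config$nMonths)) sc@nMonths <- as.integer(config$nMonths)
    if (!is.null(config$x0)) sc@x0 <- as.numeric(config$x0)
    if (!is.null(config$startCalendarMonth))
      sc@startCalendarMonth <- as.integer(config$startCalendarMonth)
    if (!is.null(config$cycloneMonths))
      sc@schedule <- CycloneSchedule(as.integer(config$cycloneMonths))
    if (!is.null(config$missingMonths))
      sc@missingMonths <- as.integer(config$missingMonths)
    perCamp <- isTRUE(config$perCamp)
    d <- simulateScenario(sc, perCamp = perCamp)
    writeCounts(d, outfile("counts.csv"))
    truth <- data.frame(monthIndex = d@counts@monthIndex,
                        calendarMonth = d@counts@calendarMonth,
                        total = d@truthStates@total,
                        inCamp = d@truthStates@inCamp)
    write.csv(truth, outfile("truth_states.csv"), row.names = FALSE,
              quote = FALSE)
    pv <- .paramsToVector(d@truthParams)
    write.csv(data.frame(parameter = names(pv), value = unname(pv)),
              outfile("truth_params.csv"), row.names = FALSE, quote = FALSE)
    artifacts <- outfile(c("counts.csv", "truth_states.csv",
                           "truth_params.csv"))
  } else if (command == "fit") {
    data <- readCounts(config$data)
    sched <- CycloneSchedule(as.integer(config$cycloneMonths %||% integer(0)))
    cfg <- McmcConfig(nChains = config$chains %||% 3L,
                      nIter = config$iter %||% 50000L,
                      nBurnin = config$burnin %||% 10000L,
                      thinStates = config$thin %||% 10L, seed = seed)
    fit <- fitSSM(data, sched, cfg)
    writeDraws(fit, outfile("draws.csv"))
    .writeStates(fit, outfile("states_total.csv"),
                 outfile("states_incamp.csv"))
    diag <- c(sprintf("rhat %s %.4f", names(rhat(fit)), rhat(fit)),
              sprintf("max rhat %.4f", max(rhat(fit))))
    writeLines(diag, outfile("diagnostics.txt"))
    artifacts <- outfile(c("draws.csv", "states_total.csv",
                           "states_incamp.csv", "diagnostics.txt"))
  } else if (command == "summarize") {
    chains <- readDraws(config$draws)
    m <- do.call(rbind, chains)
    f <- config$cycloneFrequency %||%
      stop("cycloneFrequency is required for summarize")
    rates <- rateOfIncrease(m, cycloneFrequency = f)
    qs <- quantile(rates@rWithCyclone, c(0.025, 0.5, 0.975), names = FALSE)
    rep <- data.frame(
      quantity = c("r_mean", "r_lower", "r_median", "r_upper",
                   "p_decline"),
      value = c(mean(rates@rWithCyclone), qs, rates@pDecline))
    write.csv(rep, outfile("rate_report.csv"), row.names = FALSE,
              quote = FALSE)
    artifacts <- outfile("rate_report.csv")
  } else if (command == "ddj") {
    data <- readCounts(config$data)
    res <- ddj(data, bandwidth = config$bandwidth %||% 3,
               deseasonalize = isTRUE(config$deseasonalize))
    write.csv(data.frame(time = res@time,
                         conditionalVariance = res@conditionalVariance,
                         totalVariance = res@totalVariance,
                         diffusion = res@diffusion,
                         jumpIntensity = res@jumpIntensity),
              outfile("ddj.csv"), row.names = FALSE, quote = FALSE)
    artifacts <- outfile("ddj.csv")
  } else if (command == "project") {
    fit <- .rebuildFit(config$fitDir, config$data,
                       as.integer(config$cycloneMonths %||% integer(0)))
    proj <- projectPopulation(fit, as.integer(config$horizon %||% 24L),
                              futureSchedule = if (!is.null(
                                config$futureCycloneMonths))
                                CycloneSchedule(as.integer(
                                  config$futureCycloneMonths)),
                              seed = seed)
    write.csv(cbind(proj$total,
                    inCampLower = proj$inCamp$lower,
                    inCampMedian = proj$inCamp$median,
                    inCampUpper = proj$inCamp$upper),
              outfile("projection.csv"), row.names = FALSE, quote = FALSE)
    artifacts <- outfile("projection.csv")
  }

  log <- c(sprintf("command: %s", command),
           sprintf("seed: %s", seed),
           sprintf("config_md5: %s", configHash),
           sprintf("package_version: %s", packageVersion("roostSSM")),
           sprintf("r_version: %s", getRversion()))
  writeLines(log, outfile(paste0(command, "_run.log")))
  invisible(c(artifacts, outfile(paste0(command, "_run.log"))))
}

## reconstruct a minimal PosteriorDraws from fit-stage artifacts
.rebuildFit <- function(fitDir, dataPath, cycloneMonths) {
  chains <- readDraws(file.path(fitDir, "draws.csv"))
  total <- as.matrix(read.csv(file.path(fitDir, "states_total.csv")))
  inCamp <- as.matrix(read.csv(file.path(fitDir, "states_incamp.csv")))
  data <- readCounts(dataPath)
  nPerChain <- nrow(total) / length(chains)
  thin <- max(1L, nrow(chains[[1L]]) %/% nPerChain)
  stateIter <- as.integer(seq(thin, nrow(chains[[1L]]), by = thin))
  splitRows <- rep(seq_along(chains), each = nPerChain)
  new("PosteriorDraws", paramDraws = chains,
      totalDraws = lapply(split.data.frame(log(total), splitRows),
                          as.matrix),
      inCampDraws = lapply(split.data.frame(log(inCamp), splitRows),
                           as.matrix),
      stateIterations = stateIter,
      acceptance = list(), rhat = setNames(numeric(0), character(0)),
      config = McmcConfig(nChains = length(chains),
                          nIter = nrow(chains[[1L]]), thinStates = thin),
      data = data, schedule = CycloneSchedule(cycloneMonths))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
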