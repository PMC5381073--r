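## Flat text I/O. Parameter sets travel as `key = value` lines with the
## canonical names r_P, r_C, K_P, c_P, c_C, step_minutes, steps_per_day;
## tabular data as comma-delimited text with headers.

.paramFileNames <- c(r_P = "rP", r_C = "rC", K_P = "KP", c_P = "cP",
                     c_C = "cC", step_minutes = "stepMinutes",
                     steps_per_day = "stepsPerDay")

#' Read and write model parameter sets
#'
#' Flat `key = value` text with keys \code{r_P, r_C, K_P, c_P, c_C,
#' step_minutes, steps_per_day}. Blank lines and \code{#} comments are
#' ignored on read.
#'
#' @param path file path
#' @param params [ModelParameters-class]
#' @return `readParameters()` a [ModelParameters-class];
#'   `writeParameters()` the path, invisibly
#' @examples
#' f <- tempfile(fileext = ".conf")
#' writeParameters(modelParameters(), f)
#' readParameters(f)
#' @export
readParameters <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- which(lengths(kv) != 2L)
  if (length(bad))
    stop(sprintf("malformed parameter line %d: '%s'", bad[1L], lines[bad[1L]]))
  keys <- trimws(vapply(kv, `[`, "", 1L))
  vals <- as.numeric(trimws(vapply(kv, `[`, "", 2L)))
  unknown <- setdiff(keys, names(.paramFileNames))
  if (length(unknown))
    stop("unknown parameter key(s): ", paste(unknown, collapse = ", "))
  args <- list(rP = 0.094, rC = 0.012, KP = 4.9e8, cP = 3.5e-6,
               cC = 1.4e-11, stepMinutes = 7.5, stepsPerDay = 192L)
  for (i in seq_along(keys)) {
    slotName <- .paramFileNames[[keys[i]]]
    args[[slotName]] <- if (slotName == "stepsPerDay") as.integer(vals[i])
                        else vals[i]
  }
  do.call(modelParameters, args)
}

#' @rdname readParameters
#' @export
writeParameters <- function(params, path) {
  stopifnot(is(params, "ModelParameters"))
  lines <- vapply(names(.paramFileNames), function(k) {
    sprintf("%s = %.17g", k, slot(params, .paramFileNames[[k]]))
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read and write trajectories
#'
#' Daily series as `day,prey,predator`; per-step series as
#' `step,prey,predator` (\code{what = "fine"}).
#'
#' @param traj [Trajectory-class]
#' @param path file path
#' @param what \code{"daily"} or \code{"fine"}
#' @param samplingConvention convention tag attached on read
#' @return `readTrajectory()` a [Trajectory-class]; `writeTrajectory()`
#'   the path, invisibly
#' @export
writeTrajectory <- function(traj, path, what = c("daily", "fine")) {
  stopifnot(is(traj, "Trajectory"))
  what <- match.arg(what)
  d <- if (what == "daily") traj@daily else traj@fine
  if (what == "fine" && nrow(d) == 0L)
    stop("trajectory holds no per-step output; rerun with keepFine = TRUE")
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeTrajectory
#' @export
readTrajectory <- function(path, samplingConvention = "pre_dilution") {
  d <- utils::read.csv(path)
  if (all(c("day", "prey", "predator") %in% names(d))) {
    new("Trajectory", daily = d,
        fine = data.frame(step = integer(0), prey = numeric(0),
                          predator = numeric(0)),
        samplingConvention = samplingConvention)
  } else if (all(c("step", "prey", "predator") %in% names(d))) {
    new("Trajectory",
        daily = data.frame(day = integer(0), prey = numeric(0),
                           predator = numeric(0))[FALSE, ],
        fine = d, samplingConvention = samplingConvention)
  } else {
    stop("expected columns day,prey,predator or step,prey,predator")
  }
}

#' Read and write replicated count series
#'
#' Delimited text `day,replicate,prey,predator`.
#'
#' @param obs [ObservedSeries-class]
#' @param path file path
#' @return `readObservedSeries()` an [ObservedSeries-class];
#'   `writeObservedSeries()` the path, invisibly
#' @export
writeObservedSeries <- function(obs, path) {
  stopifnot(is(obs, "ObservedSeries"))
  utils::write.csv(obs@counts, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeObservedSeries
#' @export
readObservedSeries <- function(path) {
  d <- utils::read.csv(path)
  need <- c("day", "replicate", "prey", "predator")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "))
  new("ObservedSeries", counts = d[, need])
}

#' Read and write growth-curve datasets
#'
#' All three setups in one delimited file
#' `setup,replicate,hour,prey,predator`, empty cells for the species
#' absent from a setup. Initial abundances are carried in `#`-comment
#' header lines `# init <setup> <prey> <predator>`.
#'
#' @param curves named list of [GrowthCurveData-class] (as returned by
#'   [generateGrowthCurves()])
#' @param path file path
#' @return `readGrowthCurves()` a named list of
#'   [GrowthCurveData-class]; `writeGrowthCurves()` the path, invisibly
#' @export
writeGrowthCurves <- function(curves, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (gc in curves)
    writeLines(sprintf("# init %s %.17g %.17g", gc@setup, gc@initP,
                       gc@initC), con)
  writeLines("setup,replicate,hour,prey,predator", con)
  for (gc in curves) {
    s <- gc@samples
    fmt <- function(x) ifelse(is.na(x), "", sprintf("%.17g", x))
    writeLines(sprintf("%s,%d,%g,%s,%s", gc@setup, s$replicate, s$hour,
                       fmt(s$prey), fmt(s$predator)), con)
  }
  invisible(path)
}

#' @rdname writeGrowthCurves
#' @export
readGrowthCurves <- function(path) {
  lines <- readLines(path)
  initLines <- grep("^# init ", lines, value = TRUE)
  inits <- list()
  for (l in initLines) {
    parts <- strsplit(trimws(sub("^# init ", "", l)), "[[:space:]]+")[[1L]]
    inits[[parts[1L]]] <- as.numeric(parts[2:3])
  }
  d <- utils::read.csv(text = paste(grep("^#", lines, invert = TRUE,
                                         value = TRUE), collapse = "\n"))
  need <- c("setup", "replicate", "hour", "prey", "predator")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "))
  out <- list()
  for (s in unique(d$setup)) {
    sub <- d[d$setup == s, c("replicate", "hour", "prey", "predator")]
    rownames(sub) <- NULL
    ip <- if (!is.null(inits[[s]])) inits[[s]][1L]
          else max(0, sub$prey[sub$hour == min(sub$hour)], na.rm = TRUE)
    ic <- if (!is.null(inits[[s]])) inits[[s]][2L]
          else max(0, sub$predator[sub$hour == min(sub$hour)], na.rm = TRUE)
    out[[s]] <- new("GrowthCurveData", setup = s, samples = sub,
                    initP = ip, initC = ic)
  }
  out
}

#' Read and write dilution schedules
#'
#' Delimited text `day,fold,rate`.
#'
#' @param schedule [DilutionSchedule-class]
#' @param path file path
#' @return `readSchedule()` a [DilutionSchedule-class];
#'   `writeSchedule()` the path, invisibly
#' @export
writeSchedule <- function(schedule, path) {
  stopifnot(is(schedule, "DilutionSchedule"))
  d <- data.frame(day = seq_along(schedule@folds),
                  fold = schedule@folds, rate = schedule@rates)
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeSchedule
#' @export
readSchedule <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("fold") %in% names(d))) stop("missing column: fold")
  new("DilutionSchedule", folds = d$fold, rates = foldToRate(d$fold))
}

#' Write a sweep result table
#'
#' Delimited text `value,species,recovery_days,censored`.
#'
#' @param result [SweepResult-class]
#' @param path file path
#' @return the path, invisibly
#' @export
writeSweepTable <- function(result, path) {
  stopifnot(is(result, "SweepResult"))
  t <- result@table
  out <- data.frame(value = t$value, species = t$species,
                    recovery_days = t$recoveryDays,
                    censored = tolower(as.character(t$censored)),
                    extinct = tolower(as.character(t$extinct)))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
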