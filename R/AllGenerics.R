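## Accessor generics. Slot access from user code is discouraged; these are
## the supported surface.

#' @export
setGeneric("dailySeries", function(x, ...) standardGeneric("dailySeries"))

#' @export
setGeneric("fineSeries", function(x, ...) standardGeneric("fineSeries"))

#' @export
setGeneric("modelParams", function(x, ...) standardGeneric("modelParams"))

#' @export
setGeneric("objectiveValue", function(x, ...) standardGeneric("objectiveValue"))

#' @export
setGeneric("replicateMeans", function(x, ...) standardGeneric("replicateMeans"))

#' @export
setGeneric("counts", function(x, ...) standardGeneric("counts"))

#' @export
setGeneric("scheduleRates", function(x, ...) standardGeneric("scheduleRates"))

#' @export
setGeneric("scheduleFolds", function(x, ...) standardGeneric("scheduleFolds"))

#' @export
setGeneric("sweepTable", function(x, ...) standardGeneric("sweepTable"))

#' @export
setGeneric("bandLimits", function(x, ...) standardGeneric("bandLimits"))

#' Accessors for the package's S4 containers
#'
#' Small read-only accessors: `dailySeries()` and `fineSeries()` return
#' the daily / per-step data.frame of a [Trajectory-class];
#' `counts()` the raw replicate table and `replicateMeans()` the per-day
#' replicate-mean series of an [ObservedSeries-class]; `modelParams()`
#' and `objectiveValue()` the fitted parameters and final objective of a
#' [CalibrationResult-class]; `scheduleFolds()`/`scheduleRates()` the
#' per-day columns of a [DilutionSchedule-class]; `sweepTable()` the
#' results table of a [SweepResult-class]; `bandLimits()` the
#' `c(low, high)` limits of an [EquilibriumBand-class].
#'
#' @param x the object
#' @param ... unused
#' @return see above; `replicateMeans()` returns a data.frame with
#'   columns `day`, `prey`, `predator` (and `preySD`, `predatorSD`).
#' @name accessors
#' @aliases dailySeries fineSeries modelParams objectiveValue
#'   replicateMeans counts scheduleRates scheduleFolds sweepTable
#'   bandLimits
#' @examples
#' tr <- simulateMicrocosm(modelParameters(),
#'   buildSchedule(controlRegime(), 3),
#'   populationState(3.6e7, 4.2e4))
#' head(dailySeries(tr))
NULL

setMethod("dailySeries", "Trajectory", function(x, ...) x@daily)
setMethod("fineSeries", "Trajectory", function(x, ...) x@fine)
setMethod("modelParams", "CalibrationResult", function(x, ...) x@params)
setMethod("objectiveValue", "CalibrationResult", function(x, ...) x@objectiveValue)
setMethod("counts", "ObservedSeries", function(x, ...) x@counts)
setMethod("scheduleRates", "DilutionSchedule", function(x, ...) x@rates)
setMethod("scheduleFolds", "DilutionSchedule", function(x, ...) x@folds)
setMethod("sweepTable", "SweepResult", function(x, ...) x@table)
setMethod("bandLimits", "EquilibriumBand",
          function(x, ...) c(low = x@low, high = x@high))

#' @describeIn accessors per-day replicate means and standard deviations
#'   of an observed series
#' @export
setMethod("replicateMeans", "ObservedSeries", function(x, ...) {
  cts <- x@counts
  days <- sort(unique(cts$day))
  agg <- function(v, f) vapply(days, function(d) f(v[cts$day == d]), numeric(1))
  data.frame(
    day = days,
    prey = agg(cts$prey, mean),
    predator = agg(cts$predator, mean),
    preySD = agg(cts$prey, stats::sd),
    predatorSD = agg(cts$predator, stats::sd)
  )
})

#' Coerce containers to data.frame
#'
#' @param x a [Trajectory-class] or [ObservedSeries-class]
#' @param ... unused
#' @return the daily series / the replicate count table
#' @name as.data.frame-methods
#' @export
setMethod("as.data.frame", "Trajectory", function(x, ...) x@daily)

#' @rdname as.data.frame-methods
#' @export
setMethod("as.data.frame", "ObservedSeries", function(x, ...) x@counts)

#' @export
setGeneric("nDays", function(x, ...) standardGeneric("nDays"))

#' @describeIn accessors number of simulated days covered by a schedule
#' @export
setMethod("nDays", "DilutionSchedule", function(x, ...) length(x@rates))

#' @describeIn accessors number of post-inoculation days in a trajectory
#' @export
setMethod("nDays", "Trajectory", function(x, ...) nrow(x@daily) - 1L)
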