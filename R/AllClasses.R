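#' @import methods
NULL

## Central S4 containers. All abundances are cells per ml; the model clock
## runs in steps of `stepMinutes` minutes, `stepsPerDay` steps per 24 h.

#' Model parameters for the discrete-time predator-prey map
#'
#' Holds the five dynamical parameters of the daily-dilution
#' Lotka-Volterra map -- prey growth rate \code{rP}, predator growth rate
#' \code{rC} (the coupling to the alternative dissolved resource), prey
#' carrying capacity \code{KP}, and the two interaction coefficients
#' \code{cP} (prey loss per predator) and \code{cC} (conversion of
#' consumed prey into predator growth) -- together with the time-step
#' bookkeeping. Growth rates are per time step; the default step is
#' 7.5 minutes, 192 steps per day.
#'
#' @slot rP prey growth rate per step (dimensionless)
#' @slot rC predator growth rate per step in the absence of prey;
#'   \code{rC = 0} removes the alternative-resource coupling
#' @slot KP prey carrying capacity (cells/ml)
#' @slot cP prey interaction coefficient (ml/cells per step)
#' @slot cC predator interaction coefficient (ml/cells per step)
#' @slot stepMinutes duration of one iteration, minutes
#' @slot stepsPerDay iterations per 24 h; must satisfy
#'   \code{stepsPerDay * stepMinutes == 1440}
#' @seealso [modelParameters()] for the user-facing constructor with the
#'   calibrated microcosm defaults.
#' @exportClass ModelParameters
setClass("ModelParameters",
  representation(
    rP = "numeric", rC = "numeric", KP = "numeric",
    cP = "numeric", cC = "numeric",
    stepMinutes = "numeric", stepsPerDay = "integer"
  )
)

setValidity("ModelParameters", function(object) {
  msg <- character()
  one <- function(x) length(x) == 1L && is.finite(x)
  if (!one(object@rP) || object@rP <= 0) msg <- c(msg, "rP must be a single positive number")
  if (!one(object@rC) || object@rC < 0) msg <- c(msg, "rC must be a single non-negative number")
  if (!one(object@KP) || object@KP <= 0) msg <- c(msg, "KP must be a single positive number")
  if (!one(object@cP) || object@cP < 0) msg <- c(msg, "cP must be non-negative")
  if (!one(object@cC) || object@cC < 0) msg <- c(msg, "cC must be non-negative")
  if (!one(object@stepMinutes) || object@stepMinutes <= 0)
    msg <- c(msg, "stepMinutes must be positive")
  if (length(object@stepsPerDay) != 1L || object@stepsPerDay < 1L)
    msg <- c(msg, "stepsPerDay must be a positive integer")
  if (length(msg) == 0L &&
      abs(object@stepsPerDay * object@stepMinutes - 1440) > 1e-9)
    msg <- c(msg, "stepsPerDay * stepMinutes must equal 1440 minutes")
  if (length(msg)) msg else TRUE
})

#' Population state of the two-species microcosm
#'
#' Prey and predator abundance (cells/ml) at a given model step.
#'
#' @slot P prey abundance, cells/ml
#' @slot C predator abundance, cells/ml
#' @slot t step index (0 = inoculation)
#' @exportClass PopulationState
## NB: the slot is named C (the field's symbol for the consumer), which
## partial-matches new()'s Class formal -- construct via populationState(),
## never new("PopulationState", C = ...).
setClass("PopulationState",
  representation(P = "numeric", C = "numeric", t = "integer"),
  prototype(P = 0, C = 0, t = 0L)
)

setValidity("PopulationState", function(object) {
  msg <- character()
  if (length(object@P) != 1L || !is.finite(object@P) || object@P < 0)
    msg <- c(msg, "P must be a single finite non-negative number")
  if (length(object@C) != 1L || !is.finite(object@C) || object@C < 0)
    msg <- c(msg, "C must be a single finite non-negative number")
  if (length(object@t) != 1L || object@t < 0L)
    msg <- c(msg, "t must be a single non-negative integer")
  if (length(msg)) msg else TRUE
})

#' Disturbance regime of a serially diluted microcosm
#'
#' Encodes one of the three experimental treatments: an undisturbed
#' control (constant daily fold), a press disturbance (elevated fold
#' sustained over several consecutive days) or a pulse disturbance (a
#' single severe dilution event). A fold-f transfer retains 1/f of the
#' culture.
#'
#' @slot kind one of \code{"control"}, \code{"press"}, \code{"pulse"}
#' @slot baselineFold daily dilution fold under normal operation
#' @slot disturbanceFold fold applied on disturbed days
#' @slot startDay first disturbed day (NA for control)
#' @slot durationDays number of consecutive disturbed days (0 for control;
#'   always 1 for pulse)
#' @seealso [controlRegime()], [pressRegime()], [pulseRegime()]
#' @exportClass DisturbanceRegime
setClass("DisturbanceRegime",
  representation(
    kind = "character", baselineFold = "numeric",
    disturbanceFold = "numeric", startDay = "integer",
    durationDays = "integer"
  )
)

setValidity("DisturbanceRegime", function(object) {
  msg <- character()
  if (!object@kind %in% c("control", "press", "pulse"))
    msg <- c(msg, "kind must be 'control', 'press' or 'pulse'")
  if (object@baselineFold < 1) msg <- c(msg, "baselineFold must be >= 1")
  if (object@disturbanceFold < 1) msg <- c(msg, "disturbanceFold must be >= 1")
  if (object@kind == "control") {
    if (object@durationDays != 0L)
      msg <- c(msg, "control regimes have durationDays = 0")
  } else {
    if (is.na(object@startDay) || object@startDay < 1L)
      msg <- c(msg, "disturbed regimes need startDay >= 1")
    if (object@durationDays < 1L)
      msg <- c(msg, "disturbed regimes need durationDays >= 1")
    if (object@kind == "pulse" && object@durationDays != 1L)
      msg <- c(msg, "pulse regimes have durationDays = 1")
  }
  if (length(msg)) msg else TRUE
})

#' Per-day dilution schedule
#'
#' One dilution fold (and the equivalent per-day mortality rate
#' \code{d = 1 - 1/fold}) per simulated day. The dilution event of day k
#' is applied at the first model step of day k.
#'
#' @slot folds dilution fold per day, all >= 1
#' @slot rates per-day dilution rate, \code{1 - 1/folds}
#' @seealso [buildSchedule()]
#' @exportClass DilutionSchedule
setClass("DilutionSchedule",
  representation(folds = "numeric", rates = "numeric")
)

setValidity("DilutionSchedule", function(object) {
  msg <- character()
  if (length(object@folds) != length(object@rates))
    msg <- c(msg, "folds and rates must have equal length")
  else {
    if (any(object@folds < 1)) msg <- c(msg, "all folds must be >= 1")
    if (any(abs(object@rates - (1 - 1 / object@folds)) > 1e-12))
      msg <- c(msg, "rates must equal 1 - 1/folds")
  }
  if (length(msg)) msg else TRUE
})

#' Simulated trajectory of the microcosm
#'
#' Daily samples (and optionally every model step) of prey and predator
#' abundance. Daily sampling follows the experimental convention: the
#' sample for day k is the state of the culture grown for 24 h,
#' immediately before the dilution event of day k+1
#' (\code{samplingConvention = "pre_dilution"}); day 0 is the inoculation
#' state, so \code{daily} has \code{nDays + 1} rows.
#'
#' @slot daily data.frame with columns \code{day}, \code{prey},
#'   \code{predator}
#' @slot fine data.frame with columns \code{step}, \code{prey},
#'   \code{predator} (zero rows unless per-step output was requested)
#' @slot samplingConvention \code{"pre_dilution"} or \code{"post_dilution"}
#' @exportClass Trajectory
setClass("Trajectory",
  representation(
    daily = "data.frame", fine = "data.frame",
    samplingConvention = "character"
  )
)

setValidity("Trajectory", function(object) {
  msg <- character()
  if (!all(c("day", "prey", "predator") %in% names(object@daily)))
    msg <- c(msg, "daily needs columns day, prey, predator")
  else {
    if (is.unsorted(object@daily$day, strictly = TRUE))
      msg <- c(msg, "days must be strictly increasing")
    if (any(object@daily$prey < 0) || any(object@daily$predator < 0))
      msg <- c(msg, "abundances must be non-negative")
  }
  if (!object@samplingConvention %in% c("pre_dilution", "post_dilution"))
    msg <- c(msg, "samplingConvention must be pre_dilution or post_dilution")
  if (length(msg)) msg else TRUE
})

#' Replicated daily count series
#'
#' The shape of the experimental data: for every recorded day and
#' replicate flask, one prey and one predator count (cells/ml).
#'
#' @slot counts data.frame with columns \code{day}, \code{replicate},
#'   \code{prey}, \code{predator}
#' @seealso [replicateMeans()], [generateMicrocosmCounts()]
#' @exportClass ObservedSeries
setClass("ObservedSeries", representation(counts = "data.frame"))

setValidity("ObservedSeries", function(object) {
  msg <- character()
  need <- c("day", "replicate", "prey", "predator")
  if (!all(need %in% names(object@counts)))
    msg <- c(msg, sprintf("counts needs columns %s", paste(need, collapse = ", ")))
  else if (nrow(object@counts) &&
           (any(object@counts$prey < 0, na.rm = TRUE) ||
            any(object@counts$predator < 0, na.rm = TRUE)))
    msg <- c(msg, "abundances must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Equilibrium band of a species
#'
#' The min-max envelope of a species' daily abundances over a
#' pre-disturbance window, used as the reference range for response and
#' recovery times. The window is half-open: days \code{fromDay} to
#' \code{toDay - 1}.
#'
#' @slot species label ("prey" or "predator")
#' @slot low,high band limits, cells/ml
#' @slot fromDay,toDay window, \code{toDay} exclusive
#' @seealso [equilibriumBand()]
#' @exportClass EquilibriumBand
setClass("EquilibriumBand",
  representation(
    species = "character", low = "numeric", high = "numeric",
    fromDay = "integer", toDay = "integer"
  )
)

setValidity("EquilibriumBand", function(object) {
  if (object@low > object@high) "low must be <= high" else TRUE
})

#' Hourly growth-curve data for one culture setup
#'
#' Replicated counts at sampled hours within the first 24 h of an
#' undiluted culture: prey alone, predator growing axenically (on
#' dissolved nutrients only), or both species together.
#'
#' @slot setup \code{"prey_only"}, \code{"predator_axenic"} or
#'   \code{"co_culture"}
#' @slot samples data.frame with columns \code{replicate}, \code{hour},
#'   \code{prey}, \code{predator} (NA for the species absent from the
#'   setup)
#' @slot initP,initC initial abundances, cells/ml
#' @exportClass GrowthCurveData
setClass("GrowthCurveData",
  representation(
    setup = "character", samples = "data.frame",
    initP = "numeric", initC = "numeric"
  )
)

setValidity("GrowthCurveData", function(object) {
  msg <- character()
  if (!object@setup %in% c("prey_only", "predator_axenic", "co_culture"))
    msg <- c(msg, "setup must be prey_only, predator_axenic or co_culture")
  if (!all(c("replicate", "hour", "prey", "predator") %in% names(object@samples)))
    msg <- c(msg, "samples needs columns replicate, hour, prey, predator")
  else if (nrow(object@samples) &&
           (any(object@samples$hour < 0) || any(object@samples$hour > 24)))
    msg <- c(msg, "sampled hours must lie in [0, 24]")
  if (length(msg)) msg else TRUE
})

#' Multiplicative replicate-noise model
#'
#' Lognormal multiplicative noise with mean 1: a count is the
#' deterministic model value times \code{exp(rnorm(1, -s^2/2, s))} with
#' \code{s^2 = log(1 + cv^2)}, so the expected count equals the model
#' value and the coefficient of variation equals \code{cv}. \code{cv = 0}
#' reproduces the deterministic trajectory exactly.
#'
#' @slot cv coefficient of variation, >= 0
#' @slot seed RNG seed used by the generators
#' @seealso [noiseModel()]
#' @exportClass NoiseModel
setClass("NoiseModel", representation(cv = "numeric", seed = "integer"))

setValidity("NoiseModel", function(object) {
  if (length(object@cv) != 1L || object@cv < 0) "cv must be >= 0" else TRUE
})

#' Result of a calibration stage
#'
#' @slot params fitted [ModelParameters-class]
#' @slot objectiveValue final value of the relative-distance objective
#' @slot stage \code{"growth_curve"} or \code{"lhs_refined"}
#' @slot nEvaluations objective evaluations spent
#' @slot bounds per-parameter (low, high) search box, a 2-row matrix
#' @slot seed RNG seed (NA for the deterministic growth-curve stage)
#' @slot evaluated data.frame of candidates and objectives (Latin
#'   hypercube stage only; zero rows otherwise)
#' @slot notes diagnostic messages (identifiability warnings etc.)
#' @exportClass CalibrationResult
setClass("CalibrationResult",
  representation(
    params = "ModelParameters", objectiveValue = "numeric",
    stage = "character", nEvaluations = "integer",
    bounds = "matrix", seed = "integer",
    evaluated = "data.frame", notes = "character"
  )
)

setValidity("CalibrationResult", function(object) {
  msg <- character()
  if (!object@stage %in% c("growth_curve", "lhs_refined"))
    msg <- c(msg, "stage must be growth_curve or lhs_refined")
  if (!is.finite(object@objectiveValue) || object@objectiveValue < 0)
    msg <- c(msg, "objectiveValue must be finite and non-negative")
  if (length(msg)) msg else TRUE
})

#' Transient-dynamics metrics of one scenario run
#'
#' Per-species response and recovery times relative to the
#' pre-disturbance equilibrium band, plus the windowed prey-predator
#' covariance before and during/after disturbance (the prey-release
#' diagnostic).
#'
#' @slot perSpecies data.frame with one row per species: columns
#'   \code{species}, \code{responseTime}, \code{recoveryTime},
#'   \code{recoveryCensored} (times in days; NA = undefined)
#' @slot covBefore,covDuringAfter windowed covariances of the max-scaled
#'   series (dimensionless)
#' @slot bands list of [EquilibriumBand-class], named by species
#' @exportClass TransientMetrics
setClass("TransientMetrics",
  representation(
    perSpecies = "data.frame",
    covBefore = "numeric", covDuringAfter = "numeric",
    bands = "list"
  )
)

#' Specification of a one-dimensional simulation sweep
#'
#' Varies one quantity -- press-disturbance duration, pulse-disturbance
#' fold, or the predator resource coupling \code{rC} -- while holding
#' everything else at the base scenario, and records per-species recovery
#' times.
#'
#' @slot variable \code{"press_duration"}, \code{"pulse_fold"} or
#'   \code{"r_C"}
#' @slot values strictly monotone sweep values
#' @slot baseParams [ModelParameters-class]
#' @slot baseRegime [DisturbanceRegime-class]
#' @slot init [PopulationState-class] at inoculation
#' @slot nDays simulated horizon, days
#' @slot spinUpDays days of baseline-fold serial dilution used to
#'   equilibrate the community before the disturbance protocol starts
#' @slot extinctionFloor abundances below this (cells/ml) flag the run as
#'   effectively extinct
#' @seealso [sweepSpec()], [runSweep()]
#' @exportClass SweepSpec
setClass("SweepSpec",
  representation(
    variable = "character", values = "numeric",
    baseParams = "ModelParameters", baseRegime = "DisturbanceRegime",
    init = "PopulationState", nDays = "integer",
    spinUpDays = "integer", extinctionFloor = "numeric"
  )
)

setValidity("SweepSpec", function(object) {
  msg <- character()
  if (!object@variable %in% c("press_duration", "pulse_fold", "r_C"))
    msg <- c(msg, "variable must be press_duration, pulse_fold or r_C")
  v <- object@values
  if (length(v) == 0L) msg <- c(msg, "values must be non-empty")
  else {
    if (length(v) > 1L && !(all(diff(v) > 0) || all(diff(v) < 0)))
      msg <- c(msg, "values must be strictly monotone")
    if (object@variable == "press_duration" &&
        (any(v < 1) || any(v != round(v))))
      msg <- c(msg, "press_duration values must be integers >= 1")
    if (object@variable == "pulse_fold" && any(v < 1))
      msg <- c(msg, "pulse_fold values must be >= 1")
    if (object@variable == "r_C" && any(v < 0))
      msg <- c(msg, "r_C values must be >= 0")
  }
  if (object@nDays < 1L) msg <- c(msg, "nDays must be >= 1")
  if (object@spinUpDays < 0L) msg <- c(msg, "spinUpDays must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Result of a simulation sweep
#'
#' @slot table data.frame with columns \code{value}, \code{species},
#'   \code{recoveryDays}, \code{censored}, \code{extinct}
#' @slot trajectories list of [Trajectory-class], one per sweep value
#' @slot spec the [SweepSpec-class] that produced the result
#' @exportClass SweepResult
setClass("SweepResult",
  representation(table = "data.frame", trajectories = "list",
                 spec = "SweepSpec")
)
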