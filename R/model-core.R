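#' Construct a model parameter set
#'
#' The defaults are the parameter values calibrated for the
#' \emph{E. coli} / \emph{Tetrahymena pyriformis} microcosm: prey growth
#' rate 0.094 and predator growth rate 0.012 per 7.5-minute step, prey
#' carrying capacity 4.9e8 cells/ml, interaction coefficients 3.5e-6
#' (prey loss per predator cell) and 1.4e-11 (prey-to-predator
#' conversion), iterated 192 times per day.
#'
#' @param rP prey growth rate per step
#' @param rC predator growth rate per step in the absence of prey
#'   (alternative-resource coupling); 0 disables it
#' @param KP prey carrying capacity, cells/ml
#' @param cP prey interaction coefficient, ml/cells per step
#' @param cC predator interaction coefficient, ml/cells per step
#' @param stepMinutes minutes per iteration
#' @param stepsPerDay iterations per 24 h
#' @return a [ModelParameters-class] object
#' @examples
#' p <- modelParameters()
#' p
#' modelParameters(rC = 0.007)  # weaker resource coupling
#' @export
modelParameters <- function(rP = 0.094, rC = 0.012, KP = 4.9e8,
                            cP = 3.5e-6, cC = 1.4e-11,
                            stepMinutes = 7.5, stepsPerDay = 192L) {
  new("ModelParameters", rP = rP, rC = rC, KP = KP, cP = cP, cC = cC,
      stepMinutes = stepMinutes, stepsPerDay = as.integer(stepsPerDay))
}

#' Construct a population state
#'
#' @param P prey abundance, cells/ml
#' @param C predator abundance, cells/ml
#' @param t step index (default 0, the inoculation state)
#' @return a [PopulationState-class] object
#' @examples
#' populationState(3.6e7, 4.2e4)
#' @export
populationState <- function(P, C, t = 0L) {
  obj <- new("PopulationState")
  obj@P <- as.numeric(P)
  obj@C <- as.numeric(C)
  obj@t <- as.integer(t)
  validObject(obj)
  obj
}

## One application of the map, scalar, no validation -- shared by the
## exported stepOnce() and the simulation loop.
.mapStep <- function(P, C, rP, rC, KP, cP, cC, d) {
  Pn <- (1 - d) * P + rP * P * (1 - P / KP) - cP * P * C
  Cn <- (1 - d) * C + rC * C + cC * P * C
  c(Pn, Cn)
}

#' Advance the predator-prey map by one time step
#'
#' Applies one iteration of the discrete-time map
#' \deqn{P_{t+1} = (1-d)P_t + r_P P_t (1 - P_t/K_P) - c_P P_t C_t}
#' \deqn{C_{t+1} = (1-d)C_t + r_C C_t + c_C P_t C_t}
#' where \code{d} is the dilution rate of this step (non-zero only on the
#' one step per day that carries the transfer event). Results are clamped
#' below at zero -- abundances are physical -- with a warning when
#' clamping fires.
#'
#' @param state a [PopulationState-class]
#' @param params a [ModelParameters-class]
#' @param d dilution rate for this step, in \code{[0, 1]}
#' @return the next [PopulationState-class] (step index incremented)
#' @examples
#' p <- modelParameters()
#' stepOnce(populationState(1e7, 1e4), p, d = 0)
#' @export
stepOnce <- function(state, params, d = 0) {
  stopifnot(is(state, "PopulationState"), is(params, "ModelParameters"))
  if (!is.finite(state@P) || !is.finite(state@C))
    stop("invalid state: non-finite abundance")
  if (length(d) != 1L || !is.finite(d) || d < 0 || d > 1)
    stop("dilution rate d must lie in [0, 1]")
  v <- .mapStep(state@P, state@C, params@rP, params@rC, params@KP,
                params@cP, params@cC, d)
  if (any(v < 0)) {
    warning("abundance clamped at 0 (map overshoot)")
    v[v < 0] <- 0
  }
  populationState(v[1L], v[2L], state@t + 1L)
}

## Tight simulation loop over nDays * stepsPerDay iterations. Kept free of
## S4 dispatch: calibration evaluates it thousands of times.
##
## The daily transfer is an instantaneous event -- both stocks multiplied
## by the retention fraction 1/fold (passed as `keeps`: computing 1 - d
## from d = 1 - 1/fold loses precision to cancellation) -- at the start
## ("first") or end ("last") of the day; all
## stepsPerDay map iterations then run undiluted. Folding d into one map
## step as written in the update equations would let the growth terms act
## on the undiluted stocks, which at fold 10 hands the predator an extra
## r_C * C_t (comparable to the 0.1 C_t retained) and makes it
## self-sustaining without prey: the observed coexistence equilibrium
## then cannot exist. See the methods vignette.
.coreSimulate <- function(P0, C0, rP, rC, KP, cP, cC, keeps, stepsPerDay,
                          keepFine = FALSE,
                          convention = "pre_dilution",
                          dilutionStep = "first") {
  ndays <- length(keeps)
  dailyP <- numeric(ndays + 1L)
  dailyC <- numeric(ndays + 1L)
  dailyP[1L] <- P0
  dailyC[1L] <- C0
  if (keepFine) {
    fineP <- numeric(ndays * stepsPerDay + 1L)
    fineC <- numeric(ndays * stepsPerDay + 1L)
    fineP[1L] <- P0
    fineC[1L] <- C0
  }
  first <- dilutionStep == "first"
  P <- P0; C <- C0
  clamped <- FALSE
  k <- 1L
  for (day in seq_len(ndays)) {
    keep <- keeps[day]
    if (first) {
      postP <- P * keep; postC <- C * keep
      P <- postP; C <- postC
    }
    for (s in seq_len(stepsPerDay)) {
      Pn <- P + rP * P * (1 - P / KP) - cP * P * C
      Cn <- C + rC * C + cC * P * C
      if (Pn < 0) { Pn <- 0; clamped <- TRUE }
      if (Cn < 0) { Cn <- 0; clamped <- TRUE }
      P <- Pn; C <- Cn
      if (keepFine) {
        k <- k + 1L
        fineP[k] <- P
        fineC[k] <- C
      }
    }
    if (!first) {
      preP <- P; preC <- C
      P <- P * keep; C <- C * keep
      postP <- P; postC <- C
      if (convention == "pre_dilution") {
        dailyP[day + 1L] <- preP
        dailyC[day + 1L] <- preC
      } else {
        dailyP[day + 1L] <- postP
        dailyC[day + 1L] <- postC
      }
    } else if (convention == "pre_dilution") {
      dailyP[day + 1L] <- P
      dailyC[day + 1L] <- C
    } else {
      dailyP[day + 1L] <- postP
      dailyC[day + 1L] <- postC
    }
  }
  list(
    dailyP = dailyP, dailyC = dailyC,
    fineP = if (keepFine) fineP else numeric(0),
    fineC = if (keepFine) fineC else numeric(0),
    clamped = clamped
  )
}

#' Simulate the diluted microcosm over whole days
#'
#' Iterates the predator-prey map for \code{nDays * stepsPerDay} steps.
#' The dilution event of day k (the k-th entry of the schedule) is an
#' instantaneous transfer -- both stocks multiplied by \code{1 - d} --
#' at the start of that day (default; \code{dilutionStep = "last"}
#' places it at the day's end instead), and every map iteration runs
#' undiluted. Daily samples follow the experimental sampling
#' convention: under \code{"pre_dilution"} (default) the sample for day
#' k is the culture grown for 24 h, taken immediately before the next
#' transfer; under \code{"post_dilution"} it is the state right after
#' day k's transfer. Day 0 is the inoculation state in either
#' convention.
#'
#' The run is fully deterministic: identical inputs give bit-identical
#' trajectories.
#'
#' @param params [ModelParameters-class]
#' @param schedule [DilutionSchedule-class]; must cover \code{nDays}
#' @param init [PopulationState-class] at inoculation
#' @param nDays days to simulate (default: the schedule length)
#' @param keepFine keep the per-step series as well? (memory: one row per
#'   7.5-minute step)
#' @param samplingConvention \code{"pre_dilution"} or
#'   \code{"post_dilution"}
#' @param dilutionStep which step of the day carries the dilution event,
#'   \code{"first"} or \code{"last"}
#' @return a [Trajectory-class]
#' @examples
#' tr <- simulateMicrocosm(modelParameters(),
#'   buildSchedule(controlRegime(), 10),
#'   populationState(3.6e7, 4.2e4))
#' tail(dailySeries(tr))
#' @export
simulateMicrocosm <- function(params, schedule, init,
                              nDays = NULL, keepFine = FALSE,
                              samplingConvention = c("pre_dilution",
                                                     "post_dilution"),
                              dilutionStep = c("first", "last")) {
  stopifnot(is(params, "ModelParameters"),
            is(schedule, "DilutionSchedule"),
            is(init, "PopulationState"))
  samplingConvention <- match.arg(samplingConvention)
  dilutionStep <- match.arg(dilutionStep)
  if (is.null(nDays)) nDays <- length(schedule@rates)
  nDays <- as.integer(nDays)
  if (nDays < 1L) stop("nDays must be >= 1")
  if (length(schedule@rates) < nDays)
    stop(sprintf("schedule covers %d days but nDays = %d",
                 length(schedule@rates), nDays))
  out <- .coreSimulate(init@P, init@C,
                       params@rP, params@rC, params@KP, params@cP, params@cC,
                       1 / schedule@folds[seq_len(nDays)], params@stepsPerDay,
                       keepFine = keepFine,
                       convention = samplingConvention,
                       dilutionStep = dilutionStep)
  if (out$clamped)
    warning("abundance clamped at 0 during simulation (map overshoot)")
  fine <- if (keepFine) {
    data.frame(step = 0:(nDays * params@stepsPerDay),
               prey = out$fineP, predator = out$fineC)
  } else {
    data.frame(step = integer(0), prey = numeric(0), predator = numeric(0))
  }
  new("Trajectory",
      daily = data.frame(day = 0:nDays, prey = out$dailyP,
                         predator = out$dailyC),
      fine = fine,
      samplingConvention = samplingConvention)
}

#' Closed-form axenic predator growth
#'
#' With no prey and no dilution the predator grows exponentially on the
#' alternative resource: \code{C0 * (1 + rC)^nSteps}. This closed form is
#' the independent oracle for the simulator's exponential limit.
#'
#' @param C0 initial predator abundance, cells/ml
#' @param params [ModelParameters-class] (only \code{rC} is used)
#' @param nSteps number of 7.5-minute steps, >= 0
#' @return predator abundance after \code{nSteps} steps
#' @examples
#' axenicPredatorGrowth(2500, modelParameters(), 192)  # 24 h
#' @export
axenicPredatorGrowth <- function(C0, params, nSteps) {
  stopifnot(is(params, "ModelParameters"), nSteps >= 0)
  C0 * (1 + params@rC)^nSteps
}
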