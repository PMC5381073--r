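#' Simulate one disturbance scenario and evaluate its transient metrics
#'
#' Runs the model under a regime's dilution schedule, computes each
#' species' equilibrium band over the pre-disturbance window (day
#' \code{bandFrom} until the disturbance start), and derives response
#' time, recovery time and the windowed prey-predator covariance before
#' versus during/after the disturbance. For a control regime the band
#' spans \code{bandFrom} to the end of the run and response/recovery are
#' undefined (NA): there is no disturbance to respond to.
#'
#' The during/after covariance window runs from the first disturbed day
#' to the day both species have re-entered their bands (or the end of
#' the series).
#'
#' @param params [ModelParameters-class]
#' @param regime [DisturbanceRegime-class]
#' @param init [PopulationState-class] at inoculation
#' @param nDays days to simulate
#' @param bandFrom first day of the equilibrium window, default 7
#' @param covScaling series scaling for the covariance, see
#'   [preyReleaseCovariance()]
#' @param recoveryCriterion band-return criterion, see [recoveryTime()]
#' @param bandMinHalfWidth minimum band half-width (fraction of the band
#'   midpoint), see [equilibriumBand()]
#' @param keepFine keep per-step output in the trajectory?
#' @return a list with elements \code{trajectory}
#'   ([Trajectory-class]) and \code{metrics} ([TransientMetrics-class])
#' @examples
#' sc <- runScenario(modelParameters(), pulseRegime(),
#'                   populationState(4e6, 4e3), nDays = 30)
#' sc$metrics
#' @export
runScenario <- function(params, regime, init, nDays,
                        bandFrom = 7L, covScaling = "max",
                        recoveryCriterion = c("inside", "crossing"),
                        bandMinHalfWidth = 0, keepFine = FALSE) {
  recoveryCriterion <- match.arg(recoveryCriterion)
  stopifnot(is(regime, "DisturbanceRegime"))
  sched <- buildSchedule(regime, nDays)
  traj <- simulateMicrocosm(params, sched, init, nDays,
                            keepFine = keepFine)
  d <- traj@daily
  control <- regime@kind == "control"
  bandTo <- if (control) nDays + 1L else regime@startDay
  if (bandFrom >= bandTo)
    stop("pre-disturbance window is empty; simulate more days or lower bandFrom")
  bands <- list(
    prey = equilibriumBand(d$day, d$prey, bandFrom, bandTo, "prey",
                           minHalfWidth = bandMinHalfWidth),
    predator = equilibriumBand(d$day, d$predator, bandFrom, bandTo,
                               "predator",
                               minHalfWidth = bandMinHalfWidth)
  )
  if (control) {
    per <- data.frame(
      species = c("prey", "predator"),
      responseTime = NA_integer_, recoveryTime = NA_integer_,
      recoveryCensored = FALSE
    )
    covBefore <- preyReleaseCovariance(d$prey, d$predator, d$day,
                                       bandFrom, nDays,
                                       scaling = covScaling)
    covDuringAfter <- NA_real_
  } else {
    start <- regime@startDay
    end <- disturbanceEnd(regime)
    one <- function(sp) {
      v <- d[[sp]]
      rt <- responseTime(d$day, v, bands[[sp]], start)
      rc <- recoveryTime(d$day, v, bands[[sp]], end,
                         criterion = recoveryCriterion)
      data.frame(species = sp,
                 responseTime = as.integer(rt),
                 recoveryTime = as.integer(rc),
                 recoveryCensored = isTRUE(attr(rc, "censored")))
    }
    per <- rbind(one("prey"), one("predator"))
    ## both species back in band (first such day at/after the end)
    insideBoth <- d$day >= end &
      d$prey >= bands$prey@low & d$prey <= bands$prey@high &
      d$predator >= bands$predator@low & d$predator <= bands$predator@high
    afterEnd <- if (any(insideBoth)) d$day[which(insideBoth)[1L]] else nDays
    covBefore <- preyReleaseCovariance(d$prey, d$predator, d$day,
                                       bandFrom, start - 1L,
                                       scaling = covScaling)
    covDuringAfter <- preyReleaseCovariance(d$prey, d$predator, d$day,
                                            start, max(afterEnd, start + 1L),
                                            scaling = covScaling)
  }
  metrics <- new("TransientMetrics", perSpecies = per,
                 covBefore = covBefore, covDuringAfter = covDuringAfter,
                 bands = bands)
  list(trajectory = traj, metrics = metrics)
}

#' Construct a sweep specification
#'
#' @param variable \code{"press_duration"}, \code{"pulse_fold"} or
#'   \code{"r_C"}
#' @param values sweep values, strictly monotone; defaults per variable:
#'   press durations 2-12 days (step 2), pulse folds 10^(1:6), r_C
#'   0.007-0.011 (step 0.001)
#' @param baseParams,baseRegime,init base scenario; defaults: calibrated
#'   parameters, the matching default regime (press regime for
#'   press_duration, pulse regime otherwise), control/press inoculum
#'   3.6e7 prey and 4.2e4 predator cells/ml (pulse: 4e6 and 4e3)
#' @param nDays horizon; default: 30 days past the latest disturbance
#'   end in the sweep, long enough to make censored recoveries rare
#' @param spinUpDays days of baseline serial dilution run before the
#'   disturbance protocol, so that each sweep run disturbs an
#'   equilibrated community (the experiments disturbed communities that
#'   had reached equilibrium dynamics; the damped oscillation of the
#'   calibrated map needs ~100 days to flatten below band width)
#' @param extinctionFloor cells/ml below which a run is flagged
#'   effectively extinct (the deterministic map never reaches exactly 0)
#' @return a [SweepSpec-class]
#' @examples
#' sweepSpec("pulse_fold")
#' @export
sweepSpec <- function(variable = c("press_duration", "pulse_fold", "r_C"),
                      values = NULL, baseParams = modelParameters(),
                      baseRegime = NULL, init = NULL, nDays = NULL,
                      spinUpDays = 100L, extinctionFloor = 1) {
  variable <- match.arg(variable)
  if (is.null(values))
    values <- switch(variable,
      press_duration = seq(2, 12, by = 2),
      pulse_fold = 10^(1:6),
      r_C = seq(0.007, 0.011, by = 0.001))
  if (is.null(baseRegime))
    baseRegime <- if (variable == "press_duration") pressRegime()
                  else pulseRegime()
  if (is.null(init))
    init <- if (baseRegime@kind == "pulse") populationState(4e6, 4e3)
            else populationState(3.6e7, 4.2e4)
  if (is.null(nDays)) {
    maxDur <- if (variable == "press_duration") max(values)
              else baseRegime@durationDays
    nDays <- baseRegime@startDay + maxDur + 30L
  }
  new("SweepSpec", variable = variable, values = as.numeric(values),
      baseParams = baseParams, baseRegime = baseRegime, init = init,
      nDays = as.integer(nDays), spinUpDays = as.integer(spinUpDays),
      extinctionFloor = as.numeric(extinctionFloor))
}

#' Run a one-dimensional simulation sweep
#'
#' For each sweep value the base scenario is modified -- the press
#' duration, the pulse fold, or the predator resource coupling
#' \code{r_C} -- and simulated; each run's equilibrium bands are
#' computed from that run's own pre-disturbance days (equilibria shift
#' with \code{r_C}, so bands are never shared across runs). Each run
#' first equilibrates the community under the baseline dilution for
#' \code{spinUpDays} (using that run's own parameters) and applies the
#' disturbance protocol to the equilibrated state. Recovery
#' times are reported per species with explicit censoring; runs whose
#' minimum abundance falls below the extinction floor are flagged
#' \code{extinct} but still reported.
#'
#' @param spec a [SweepSpec-class]
#' @param bandFrom first day of the per-run equilibrium window
#' @param recoveryCriterion band-return criterion, default
#'   \code{"crossing"} (see [recoveryTime()]): recovery-time curves
#'   compare the return to pre-disturbance size across runs, and the
#'   crossing criterion keeps that comparison free of band-overshoot
#'   artifacts
#' @param bandMinHalfWidth minimum band half-width as a fraction of the
#'   band midpoint, default 0.05: an equilibrated deterministic run has
#'   near-zero daily range, and recovery to a zero-width target never
#'   completes (see [equilibriumBand()])
#' @return a [SweepResult-class]
#' @examples
#' \donttest{
#' res <- runSweep(sweepSpec("r_C"))
#' subset(sweepTable(res), species == "predator")
#' }
#' @export
runSweep <- function(spec, bandFrom = 7L,
                     recoveryCriterion = c("crossing", "inside"),
                     bandMinHalfWidth = 0.05) {
  recoveryCriterion <- match.arg(recoveryCriterion)
  stopifnot(is(spec, "SweepSpec"))
  rows <- list()
  trajs <- list()
  for (i in seq_along(spec@values)) {
    v <- spec@values[i]
    params <- spec@baseParams
    regime <- spec@baseRegime
    if (spec@variable == "press_duration") {
      regime <- disturbanceRegime("press", regime@baselineFold,
                                  regime@disturbanceFold,
                                  regime@startDay, as.integer(v))
    } else if (spec@variable == "pulse_fold") {
      regime <- disturbanceRegime(regime@kind, regime@baselineFold,
                                  v, regime@startDay,
                                  regime@durationDays)
    } else {  # r_C
      params <- modelParameters(rP = params@rP, rC = v, KP = params@KP,
                                cP = params@cP, cC = params@cC,
                                stepMinutes = params@stepMinutes,
                                stepsPerDay = params@stepsPerDay)
    }
    init <- spec@init
    if (spec@spinUpDays > 0L) {
      spin <- simulateMicrocosm(
        params, buildSchedule(controlRegime(regime@baselineFold),
                              spec@spinUpDays),
        init)
      last <- spin@daily[nrow(spin@daily), ]
      init <- populationState(last$prey, last$predator)
    }
    sc <- runScenario(params, regime, init, spec@nDays,
                      bandFrom = bandFrom,
                      recoveryCriterion = recoveryCriterion,
                      bandMinHalfWidth = bandMinHalfWidth)
    d <- sc$trajectory@daily
    extinct <- min(d$prey[-1]) < spec@extinctionFloor ||
               min(d$predator[-1]) < spec@extinctionFloor
    per <- sc$metrics@perSpecies
    per$value <- v
    per$extinct <- extinct
    rows[[i]] <- per[, c("value", "species", "recoveryTime",
                         "recoveryCensored", "extinct")]
    trajs[[i]] <- sc$trajectory
  }
  tab <- do.call(rbind, rows)
  names(tab)[names(tab) == "recoveryTime"] <- "recoveryDays"
  names(tab)[names(tab) == "recoveryCensored"] <- "censored"
  rownames(tab) <- NULL
  names(trajs) <- as.character(spec@values)
  new("SweepResult", table = tab, trajectories = trajs, spec = spec)
}
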