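## External <-> slot name map for the five fitted parameters; the external
## names are the ones used in config files and reports.
.fitParamNames <- c(r_P = "rP", r_C = "rC", K_P = "KP", c_P = "cP", c_C = "cC")

#' Default search bounds for growth-curve calibration
#'
#' Reasonably wide positive ranges around microbially plausible values:
#' per-step growth rates, a carrying capacity spanning 1e7-5e9 cells/ml,
#' and interaction coefficients spanning four decades.
#'
#' @return a 2 x 5 matrix, rows \code{low}/\code{high}, columns
#'   \code{r_P, r_C, K_P, c_P, c_C}
#' @export
defaultCalibrationBounds <- function() {
  m <- rbind(
    low  = c(r_P = 0.01, r_C = 1e-3, K_P = 1e7, c_P = 1e-8, c_C = 1e-13),
    high = c(r_P = 0.50, r_C = 1e-1, K_P = 5e9, c_P = 1e-4, c_C = 1e-9)
  )
  m
}

#' Relative-distance power objective
#'
#' The calibration objective: the sum over all compared counts of the
#' absolute relative distance raised to an even power,
#' \eqn{\sum_i |(m_i - o_i)/o_i|^k}, default k = 4. The per-point
#' fourth power concentrates the fit on the worst-matched counts.
#' Observed zeros are excluded (relative distance undefined) with a
#' warning.
#'
#' @param model model values at the compared points
#' @param observed matching observed counts
#' @param exponent even integer >= 2, default 4
#' @return non-negative scalar; 0 iff the fit is perfect on all compared
#'   points
#' @examples
#' relativePowerObjective(c(2, 1), c(1, 1))        # |1|^4 + 0 = 1
#' relativePowerObjective(c(1.5, 0.5), c(1, 1))    # 2 * 0.5^4 = 0.125
#' @export
relativePowerObjective <- function(model, observed, exponent = 4) {
  if (length(model) != length(observed))
    stop("model and observed must have equal length")
  if (exponent < 2 || exponent %% 2 != 0)
    stop("exponent must be an even integer >= 2")
  keep <- observed != 0
  if (!all(keep)) {
    warning(sprintf("%d zero observed count(s) excluded from the objective",
                    sum(!keep)))
    model <- model[keep]
    observed <- observed[keep]
  }
  if (!length(model)) return(0)
  if (any(!is.finite(model))) return(Inf)
  sum(abs((model - observed) / observed)^exponent)
}

## Simulate an undiluted 24 h growth experiment and return model values at
## the sampled hours. Hours must fall on model steps.
.growthCurveModel <- function(rP, rC, KP, cP, cC, initP, initC, hours,
                              stepMinutes, stepsPerDay) {
  steps <- hours * 60 / stepMinutes
  if (any(abs(steps - round(steps)) > 1e-9))
    stop("sampled hours must fall on model steps")
  steps <- as.integer(round(steps))
  out <- .coreSimulate(initP, initC, rP, rC, KP, cP, cC,
                       keeps = 1, stepsPerDay = max(steps),
                       keepFine = TRUE)
  list(P = out$fineP[steps + 1L], C = out$fineC[steps + 1L])
}

## Nelder-Mead in log-parameter space, restarted from a deterministic
## ladder of multi-scale offsets around the start (growth curves sampled
## late in the day saturate, leaving plateaus where a single start can
## strand the simplex; the zero-residual basin wins any best-of
## comparison). fn takes the natural-scale parameter vector.
.nmFit <- function(fn, start, lower, upper,
                   reltol = 1e-10, maxit = 2000, restarts = 5) {
  nEval <- 0L
  wrapped <- function(lp) {
    p <- pmin(pmax(exp(lp), lower), upper)
    nEval <<- nEval + 1L
    v <- fn(p)
    if (!is.finite(v)) v <- .Machine$double.xmax / 1e10
    v
  }
  ## deterministic offsets keep this stage seed-free
  jitters <- list(0, -0.6, 0.6, -1.5, 1.5, -2.5, 2.5)
  best <- NULL
  for (r in seq_len(restarts)) {
    lp0 <- log(start) + jitters[[((r - 1L) %% length(jitters)) + 1L]]
    fit <- suppressWarnings(stats::optim(
      lp0, wrapped, method = "Nelder-Mead",
      control = list(reltol = reltol, maxit = maxit)
    ))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  ## polish the winner once from its own optimum
  fit <- suppressWarnings(stats::optim(
    log(pmin(pmax(exp(best$par), lower), upper)), wrapped,
    method = "Nelder-Mead",
    control = list(reltol = reltol, maxit = maxit)
  ))
  if (fit$value < best$value) best <- fit
  list(par = pmin(pmax(exp(best$par), lower), upper),
       value = best$value, nEval = nEval,
       converged = best$convergence == 0L)
}

#' Two-stage growth-curve calibration
#'
#' Reproduces the staged estimation design: growth rates and the prey
#' carrying capacity are fitted to the single-species growth curves,
#' then the interaction coefficients to the co-culture curve, by
#' Nelder-Mead minimisation of the relative-distance power objective.
#' Stage 1 fits \code{(r_P, K_P)} to the prey-only curve and \code{r_C}
#' to the axenic predator curve; stage 2 holds those fixed and fits
#' \code{(c_P, c_C)} to the co-culture. Simulations for every candidate
#' run undiluted over 24 h at the model's native step; the objective
#' compares model values to every replicate count (not replicate means),
#' both species where present. Parameters are optimised in log space
#' (positivity) from several deterministically offset starts, keeping
#' the best; multi-start matters because late-day samples of a
#' saturating growth curve leave near-flat objective plateaus.
#'
#' @param preyOnly,predatorAxenic,coCulture [GrowthCurveData-class] for
#'   the three setups
#' @param bounds search box, as [defaultCalibrationBounds()]
#' @param exponent objective exponent, default 4
#' @param reltol Nelder-Mead relative convergence tolerance on the
#'   objective
#' @param maxit evaluation cap per stage
#' @param restarts restarts per stage, drawn from a deterministic
#'   multi-scale offset ladder around the start
#' @param stepMinutes,stepsPerDay model clock of the fitted parameter set
#' @return a [CalibrationResult-class] with \code{stage =
#'   "growth_curve"}; \code{notes} carries identifiability warnings
#'   (e.g. a prey series flat at its initial abundance leaves
#'   \code{r_P} unidentified)
#' @seealso [refineLatinHypercube()] for the second calibration phase
#' @export
fitGrowthCurves <- function(preyOnly, predatorAxenic, coCulture,
                            bounds = defaultCalibrationBounds(),
                            exponent = 4, reltol = 1e-10, maxit = 2000,
                            restarts = 5,
                            stepMinutes = 7.5, stepsPerDay = 192L) {
  stopifnot(is(preyOnly, "GrowthCurveData"),
            is(predatorAxenic, "GrowthCurveData"),
            is(coCulture, "GrowthCurveData"))
  for (gc in list(preyOnly, predatorAxenic, coCulture))
    if (length(unique(gc@samples$hour)) < 3L)
      stop("each growth-curve setup needs >= 3 time points")
  if (any(!is.finite(bounds)) || any(bounds <= 0))
    stop("bounds must be finite and positive")
  notes <- character()
  totEval <- 0L

  ## objective against all replicate counts of one setup
  stageObjective <- function(gc, modelFor, species) {
    smp <- gc@samples
    hours <- sort(unique(smp$hour))
    function(p) {
      m <- modelFor(p, hours)
      obj <- 0
      for (sp in species) {
        obs <- smp[[sp]]
        ok <- !is.na(obs)
        if (!any(ok)) next
        mv <- m[[sp]][match(smp$hour[ok], hours)]
        obj <- obj + relativePowerObjective(mv, obs[ok], exponent)
      }
      obj
    }
  }

  ## stage 1a: (r_P, K_P) from the prey-only curve
  preyCounts <- preyOnly@samples$prey
  if (stats::sd(preyCounts) < 1e-9 * mean(preyCounts) &&
      abs(mean(preyCounts) - preyOnly@initP) < 1e-9 * preyOnly@initP) {
    notes <- c(notes, paste(
      "prey-only series is constant at the initial abundance:",
      "r_P is unidentifiable (any growth rate fits)"))
    warning(notes[length(notes)])
  }
  obj1a <- stageObjective(
    preyOnly,
    function(p, hours) {
      m <- .growthCurveModel(p[1], 0, p[2], 0, 0,
                             preyOnly@initP, 0, hours,
                             stepMinutes, stepsPerDay)
      list(prey = m$P)
    }, "prey")
  f1a <- .nmFit(obj1a,
                start = sqrt(bounds["low", c("r_P", "K_P")] *
                             bounds["high", c("r_P", "K_P")]),
                lower = bounds["low", c("r_P", "K_P")],
                upper = bounds["high", c("r_P", "K_P")],
                reltol = reltol, maxit = maxit, restarts = restarts)
  totEval <- totEval + f1a$nEval
  rP <- f1a$par[[1]]; KP <- f1a$par[[2]]

  ## stage 1b: r_C from the axenic predator curve
  obj1b <- stageObjective(
    predatorAxenic,
    function(p, hours) {
      m <- .growthCurveModel(1e-6, p[1], 1, 0, 0,
                             0, predatorAxenic@initC, hours,
                             stepMinutes, stepsPerDay)
      list(predator = m$C)
    }, "predator")
  f1b <- .nmFit(obj1b,
                start = sqrt(bounds["low", "r_C"] * bounds["high", "r_C"]),
                lower = bounds["low", "r_C"],
                upper = bounds["high", "r_C"],
                reltol = reltol, maxit = maxit, restarts = restarts)
  totEval <- totEval + f1b$nEval
  rC <- f1b$par[[1]]

  ## stage 2: (c_P, c_C) from the co-culture, stage-1 estimates fixed
  obj2 <- stageObjective(
    coCulture,
    function(p, hours) {
      m <- .growthCurveModel(rP, rC, KP, p[1], p[2],
                             coCulture@initP, coCulture@initC, hours,
                             stepMinutes, stepsPerDay)
      list(prey = m$P, predator = m$C)
    }, c("prey", "predator"))
  f2 <- .nmFit(obj2,
               start = sqrt(bounds["low", c("c_P", "c_C")] *
                            bounds["high", c("c_P", "c_C")]),
               lower = bounds["low", c("c_P", "c_C")],
               upper = bounds["high", c("c_P", "c_C")],
               reltol = reltol, maxit = maxit, restarts = restarts)
  totEval <- totEval + f2$nEval
  if (!f1a$converged || !f1b$converged || !f2$converged) {
    notes <- c(notes, "optimizer hit the evaluation cap; best-found returned")
    warning(notes[length(notes)])
  }

  new("CalibrationResult",
      params = modelParameters(rP = rP, rC = rC, KP = KP,
                               cP = f2$par[[1]], cC = f2$par[[2]],
                               stepMinutes = stepMinutes,
                               stepsPerDay = stepsPerDay),
      objectiveValue = f1a$value + f1b$value + f2$value,
      stage = "growth_curve", nEvaluations = totEval,
      bounds = bounds, seed = NA_integer_,
      evaluated = data.frame(), notes = notes)
}

#' Latin-hypercube refinement against the control time series
#'
#' Second calibration phase: draws a Latin hypercube of parameter sets
#' in a narrow box around the growth-curve estimates -- each free
#' parameter ranges over \code{[p (1 - halfWidth), p (1 + halfWidth)]}
#' -- simulates the control regime for each, and selects the set that
#' minimises the relative-distance power objective against all daily
#' counts (both species, every replicate, every observation day). This
#' absorbs drift in conditions between the growth experiments and the
#' serial-dilution experiment. The start point itself is evaluated too
#' (\code{includeStart = TRUE}), so refinement never returns a worse fit
#' than the start.
#'
#' @param start [ModelParameters-class] around which to search (the
#'   growth-curve fit)
#' @param controlObs [ObservedSeries-class] of the control treatment;
#'   must cover at least 7 days
#' @param regime [DisturbanceRegime-class], normally [controlRegime()]
#' @param halfWidth relative half-width of the box, in (0, 1); default
#'   0.2
#' @param nSamples Latin-hypercube points, default 500
#' @param seed RNG seed (recorded in the result)
#' @param exponent objective exponent, default 4
#' @param init [PopulationState-class] at inoculation; default: the
#'   day-0 replicate means of \code{controlObs}
#' @param freeze parameter names (external form, e.g. \code{"K_P"}) held
#'   at their start values
#' @param includeStart evaluate the start point alongside the hypercube?
#' @return a [CalibrationResult-class] with \code{stage = "lhs_refined"};
#'   \code{evaluated} holds every candidate and its objective
#' @export
refineLatinHypercube <- function(start, controlObs, regime = controlRegime(),
                                 halfWidth = 0.2, nSamples = 500,
                                 seed = 1, exponent = 4, init = NULL,
                                 freeze = character(),
                                 includeStart = TRUE) {
  stopifnot(is(start, "ModelParameters"), is(controlObs, "ObservedSeries"),
            is(regime, "DisturbanceRegime"))
  if (halfWidth <= 0 || halfWidth >= 1) stop("halfWidth must lie in (0, 1)")
  if (nSamples < 1) stop("nSamples must be >= 1")
  cts <- controlObs@counts
  obsDays <- sort(unique(cts$day))
  if (max(obsDays) - min(obsDays) < 7)
    stop("control observations must cover at least 7 days")
  if (is.null(init)) {
    if (!0 %in% obsDays)
      stop("controlObs has no day 0; supply init explicitly")
    d0 <- cts[cts$day == 0, ]
    init <- populationState(mean(d0$prey), mean(d0$predator))
  }
  nd <- max(obsDays)
  sched <- buildSchedule(regime, max(nd, 1L))
  fitDays <- obsDays[obsDays > 0]  # day 0 is the inoculum, not a fit point

  extNames <- names(.fitParamNames)
  bad <- setdiff(freeze, extNames)
  if (length(bad)) stop("unknown parameter(s) in freeze: ",
                        paste(bad, collapse = ", "))
  free <- setdiff(extNames, freeze)
  p0 <- vapply(extNames, function(n) slot(start, .fitParamNames[[n]]),
               numeric(1))
  lower <- p0 * (1 - halfWidth)
  upper <- p0 * (1 + halfWidth)
  bounds <- rbind(low = lower, high = upper)

  evalCandidate <- function(p) {
    out <- .coreSimulate(init@P, init@C,
                         p[["r_P"]], p[["r_C"]], p[["K_P"]],
                         p[["c_P"]], p[["c_C"]],
                         1 / sched@folds, start@stepsPerDay)
    mP <- out$dailyP[fitDays + 1L]
    mC <- out$dailyC[fitDays + 1L]
    sub <- cts[cts$day %in% fitDays, ]
    i <- match(sub$day, fitDays)
    relativePowerObjective(c(mP[i], mC[i]), c(sub$prey, sub$predator),
                           exponent)
  }

  set.seed(seed)
  u <- lhs::randomLHS(as.integer(nSamples), length(free))
  cand <- matrix(rep(p0, each = nSamples), nrow = nSamples,
                 dimnames = list(NULL, extNames))
  for (j in seq_along(free)) {
    nm <- free[j]
    cand[, nm] <- lower[[nm]] + u[, j] * (upper[[nm]] - lower[[nm]])
  }
  if (includeStart) cand <- rbind(cand, start = p0)
  rownames(cand) <- NULL

  objs <- unname(apply(cand, 1L, evalCandidate))
  if (all(!is.finite(objs)))
    stop("all candidates produced non-finite objectives; first failure: ",
         "candidate 1 overflowed the simulation")
  bestIdx <- which.min(objs)
  best <- cand[bestIdx, ]

  new("CalibrationResult",
      params = modelParameters(rP = best[["r_P"]], rC = best[["r_C"]],
                               KP = best[["K_P"]], cP = best[["c_P"]],
                               cC = best[["c_C"]],
                               stepMinutes = start@stepMinutes,
                               stepsPerDay = start@stepsPerDay),
      objectiveValue = unname(objs[bestIdx]),
      stage = "lhs_refined", nEvaluations = length(objs),
      bounds = bounds, seed = as.integer(seed),
      evaluated = data.frame(cand, objective = objs,
                             check.names = FALSE),
      notes = if (bestIdx > nSamples && includeStart)
        "no hypercube candidate improved on the start" else character())
}
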