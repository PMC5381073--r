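#' Construct a noise model
#'
#' @param cv coefficient of variation of the multiplicative lognormal
#'   replicate noise; 0 = noise-free
#' @param seed RNG seed used by the generators
#' @return a [NoiseModel-class]
#' @examples
#' noiseModel(0.1, seed = 42)
#' @export
noiseModel <- function(cv = 0.1, seed = 1L) {
  new("NoiseModel", cv = as.numeric(cv), seed = as.integer(seed))
}

## mean-1 lognormal factors: sigma^2 = log(1 + cv^2); cv = 0 gives exactly 1
.noiseFactors <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  s <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -s^2 / 2, sdlog = s)
}

#' Generate replicated daily microcosm counts
#'
#' Emulates the experimental data: the deterministic model trajectory
#' under a dilution regime, observed in \code{nReplicates} flasks with
#' independent multiplicative lognormal noise per day, species and
#' replicate. The noise has mean 1, so the expected count equals the
#' deterministic value; \code{cv = 0} reproduces it exactly. Output is
#' seed-reproducible.
#'
#' @param params [ModelParameters-class]
#' @param regime [DisturbanceRegime-class]
#' @param init [PopulationState-class] at inoculation
#' @param nDays days to simulate
#' @param nReplicates replicate flasks, default 3 (the experimental
#'   design)
#' @param noise [NoiseModel-class]
#' @return an [ObservedSeries-class] covering days 0..nDays
#' @examples
#' obs <- generateMicrocosmCounts(modelParameters(), controlRegime(),
#'   populationState(3.6e7, 4.2e4), nDays = 10,
#'   noise = noiseModel(0.1, seed = 7))
#' head(counts(obs))
#' @export
generateMicrocosmCounts <- function(params, regime, init, nDays,
                                    nReplicates = 3,
                                    noise = noiseModel()) {
  stopifnot(is(noise, "NoiseModel"), nReplicates >= 1)
  traj <- simulateMicrocosm(params, buildSchedule(regime, nDays), init,
                            nDays)
  d <- traj@daily
  set.seed(noise@seed)
  reps <- lapply(seq_len(nReplicates), function(r) {
    n <- nrow(d)
    data.frame(
      day = d$day, replicate = r,
      prey = d$prey * .noiseFactors(n, noise@cv),
      predator = d$predator * .noiseFactors(n, noise@cv)
    )
  })
  new("ObservedSeries", counts = do.call(rbind, reps))
}

#' Generate hourly growth-curve datasets
#'
#' Produces the three 24-hour growth experiments the calibration stage
#' consumes: prey alone (predator forced to zero), predator growing
#' axenically on the dissolved resource (prey forced to zero), and the
#' co-culture -- each undiluted, sampled at the given hours, replicated
#' with multiplicative lognormal noise. Defaults follow the
#' experimental protocol: samples at 12, 14, ..., 24 h, inocula of
#' 4e6 prey and 2500 predator cells/ml.
#'
#' @param params [ModelParameters-class] (the generating truth)
#' @param samplingHours hours in (0, 24] falling on model steps
#' @param initP,initC inoculum sizes, cells/ml
#' @param nReplicates replicate cultures per setup, default 3
#' @param noise [NoiseModel-class]
#' @return named list of three [GrowthCurveData-class]:
#'   \code{prey_only}, \code{predator_axenic}, \code{co_culture}
#' @examples
#' gcs <- generateGrowthCurves(modelParameters(), noise = noiseModel(0))
#' gcs$predator_axenic
#' @export
generateGrowthCurves <- function(params,
                                 samplingHours = seq(12, 24, by = 2),
                                 initP = 4e6, initC = 2500,
                                 nReplicates = 3,
                                 noise = noiseModel()) {
  stopifnot(is(params, "ModelParameters"), is(noise, "NoiseModel"))
  if (any(samplingHours <= 0) || any(samplingHours > 24))
    stop("sampling hours must lie in (0, 24]")
  model <- function(p0, c0) {
    .growthCurveModel(params@rP, params@rC, params@KP, params@cP,
                      params@cC, p0, c0, samplingHours,
                      params@stepMinutes, params@stepsPerDay)
  }
  set.seed(noise@seed)
  build <- function(setup, p0, c0) {
    m <- model(p0, c0)
    hasP <- p0 > 0
    hasC <- c0 > 0
    reps <- lapply(seq_len(nReplicates), function(r) {
      n <- length(samplingHours)
      data.frame(
        replicate = r, hour = samplingHours,
        prey = if (hasP) m$P * .noiseFactors(n, noise@cv) else NA_real_,
        predator = if (hasC) m$C * .noiseFactors(n, noise@cv)
                   else NA_real_
      )
    })
    new("GrowthCurveData", setup = setup,
        samples = do.call(rbind, reps), initP = p0, initC = c0)
  }
  list(
    prey_only = build("prey_only", initP, 0),
    predator_axenic = build("predator_axenic", 0, initC),
    co_culture = build("co_culture", initP, initC)
  )
}
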