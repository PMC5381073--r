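test_that("relative-power objective matches hand-evaluated cases", {
  expect_identical(relativePowerObjective(c(1, 2, 3), c(1, 2, 3)), 0)
  # one point, model twice the observation: |1|^4
  expect_identical(relativePowerObjective(2, 1), 1)
  # relative errors +0.5 and -0.5: 2 * 0.5^4
  expect_equal(relativePowerObjective(c(1.5, 0.5), c(1, 1)), 0.125)
  # exponent is configurable (squared-relative variant)
  expect_equal(relativePowerObjective(c(1.5, 0.5), c(1, 1), exponent = 2),
               0.5)
  expect_error(relativePowerObjective(1, 1, exponent = 3), "even")
  # zero observations excluded with a warning, not poisoning the sum
  expect_warning(v <- relativePowerObjective(c(2, 2), c(1, 0)), "zero")
  expect_identical(v, 1)
})

test_that("axenic predator curve with exact exponential data recovers r_C", {
  p <- microParams()
  gcs <- generateGrowthCurves(p, noise = noiseModel(0))
  # data lie exactly on C0 (1 + rC)^steps
  hours <- unique(gcs$predator_axenic@samples$hour)
  expect_equal(gcs$predator_axenic@samples$predator[1:7],
               axenicPredatorGrowth(2500, p, hours * 8))
  fit <- fitGrowthCurves(gcs$prey_only, gcs$predator_axenic,
                         gcs$co_culture)
  expect_equal(fit@params@rC, 0.012, tolerance = 1e-4)
})

test_that("full growth-curve calibration recovers generating parameters", {
  p <- microParams()
  gcs <- generateGrowthCurves(p, noise = noiseModel(0))
  fit <- fitGrowthCurves(gcs$prey_only, gcs$predator_axenic,
                         gcs$co_culture)
  expect_s4_class(fit, "CalibrationResult")
  expect_identical(fit@stage, "growth_curve")
  got <- c(fit@params@rP, fit@params@rC, fit@params@KP,
           fit@params@cP, fit@params@cC)
  truth <- c(p@rP, p@rC, p@KP, p@cP, p@cC)
  expect_lt(max(abs(got - truth) / truth), 0.05)
  expect_lt(fit@objectiveValue, 1e-6)
})

test_that("a prey series flat at its inoculum flags r_P unidentifiable", {
  p <- microParams()
  gcs <- generateGrowthCurves(p, initP = p@KP, noise = noiseModel(0))
  # prey-only at carrying capacity stays exactly there
  expect_true(all(gcs$prey_only@samples$prey == p@KP))
  expect_warning(
    fit <- fitGrowthCurves(gcs$prey_only, gcs$predator_axenic,
                           gcs$co_culture),
    "unidentifiable")
  expect_match(fit@notes, "unidentifiable", all = FALSE)
})

test_that("Latin hypercube candidates stratify each free parameter", {
  p <- microParams()
  obs <- generateMicrocosmCounts(p, controlRegime(), controlInit(), 10,
                                 noise = noiseModel(0))
  n <- 40
  ref <- refineLatinHypercube(p, obs, nSamples = n, seed = 5,
                              includeStart = FALSE)
  ev <- ref@evaluated
  for (nm in c("r_P", "r_C", "K_P", "c_P", "c_C")) {
    lo <- ref@bounds["low", nm]; hi <- ref@bounds["high", nm]
    strata <- floor((ev[[nm]] - lo) / (hi - lo) * n)
    strata[strata == n] <- n - 1  # the upper edge belongs to the last stratum
    expect_equal(sort(strata), 0:(n - 1))
  }
})

test_that("LHS refinement is seed-reproducible and respects the freeze mask", {
  p <- microParams()
  obs <- generateMicrocosmCounts(p, controlRegime(), controlInit(), 10,
                                 noise = noiseModel(0.05, seed = 3))
  a <- refineLatinHypercube(p, obs, nSamples = 30, seed = 7)
  b <- refineLatinHypercube(p, obs, nSamples = 30, seed = 7)
  expect_identical(a@evaluated, b@evaluated)
  expect_identical(modelParams(a), modelParams(b))
  expect_identical(a@seed, 7L)

  frozen <- refineLatinHypercube(p, obs, nSamples = 10, seed = 7,
                                 freeze = c("K_P", "c_C"))
  expect_true(all(frozen@evaluated$K_P == p@KP))
  expect_true(all(frozen@evaluated$c_C == p@cC))
  expect_false(all(frozen@evaluated$r_P == p@rP))
  expect_error(refineLatinHypercube(p, obs, nSamples = 5, seed = 1,
                                    freeze = "K_p"), "unknown parameter")
})

test_that("refinement never worsens a noise-free perfect start", {
  p <- microParams()
  obs <- generateMicrocosmCounts(p, controlRegime(), controlInit(), 10,
                                 noise = noiseModel(0))
  ref <- refineLatinHypercube(p, obs, nSamples = 25, seed = 2)
  # start is the generating truth: objective 0 is attainable and kept
  expect_identical(objectiveValue(ref), 0)
  expect_equal(modelParams(ref), p)
  # with the start excluded, a single arbitrary sample is returned as-is
  one <- refineLatinHypercube(p, obs, nSamples = 1, seed = 2,
                              includeStart = FALSE)
  expect_identical(nrow(one@evaluated), 1L)
  expect_gt(objectiveValue(one), 0)
})

test_that("LHS refinement improves the fit from a perturbed start", {
  p <- microParams()
  obs <- generateMicrocosmCounts(p, controlRegime(), controlInit(), 21,
                                 noise = noiseModel(0.1, seed = 11))
  pert <- modelParameters(rP = p@rP * 1.15, rC = p@rC * 0.85,
                          KP = p@KP * 1.15, cP = p@cP * 0.85,
                          cC = p@cC * 1.15)
  ref <- refineLatinHypercube(pert, obs, halfWidth = 0.2,
                              nSamples = 300, seed = 42)
  expect_identical(ref@stage, "lhs_refined")

  # Nash-Sutcliffe against the truth-generated replicate means improves
  means <- replicateMeans(obs)
  nd <- max(means$day)
  fitDays <- means$day[means$day > 0]
  evalE <- function(pp) {
    d <- dailySeries(simulateMicrocosm(
      pp, buildSchedule(controlRegime(), nd),
      populationState(means$prey[means$day == 0],
                      means$predator[means$day == 0])))
    nashSutcliffe(d$prey[match(fitDays, d$day)],
                  means$prey[match(fitDays, means$day)]) +
      nashSutcliffe(d$predator[match(fitDays, d$day)],
                    means$predator[match(fitDays, means$day)])
  }
  expect_gt(evalE(modelParams(ref)), evalE(pert))
})
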