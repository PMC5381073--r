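.fmtNum <- function(x) formatC(x, format = "g", digits = 4)

setMethod("show", "ModelParameters", function(object) {
  cat("ModelParameters (per", object@stepMinutes, "min step,",
      object@stepsPerDay, "steps/day)\n")
  cat(sprintf("  r_P = %s  K_P = %s cells/ml\n",
              .fmtNum(object@rP), .fmtNum(object@KP)))
  cat(sprintf("  r_C = %s  (alternative-resource coupling)\n",
              .fmtNum(object@rC)))
  cat(sprintf("  c_P = %s  c_C = %s ml/cells\n",
              .fmtNum(object@cP), .fmtNum(object@cC)))
})

setMethod("show", "PopulationState", function(object) {
  cat(sprintf("PopulationState: P = %s, C = %s cells/ml (step %d)\n",
              .fmtNum(object@P), .fmtNum(object@C), object@t))
})

setMethod("show", "DisturbanceRegime", function(object) {
  if (object@kind == "control") {
    cat(sprintf("DisturbanceRegime: control, %g-fold daily dilution\n",
                object@baselineFold))
  } else {
    cat(sprintf(
      "DisturbanceRegime: %s, %g-fold on days %d-%d (baseline %g-fold)\n",
      object@kind, object@disturbanceFold, object@startDay,
      object@startDay + object@durationDays - 1L, object@baselineFold))
  }
})

setMethod("show", "DilutionSchedule", function(object) {
  n <- length(object@folds)
  cat(sprintf("DilutionSchedule: %d days, folds %s\n", n,
              paste(unique(object@folds), collapse = "/")))
})

setMethod("show", "Trajectory", function(object) {
  nd <- nrow(object@daily) - 1L
  cat(sprintf("Trajectory: %d days (%s sampling)%s\n", nd,
              object@samplingConvention,
              if (nrow(object@fine)) ", per-step output kept" else ""))
  if (nd >= 0) {
    last <- object@daily[nrow(object@daily), ]
    cat(sprintf("  day %d: prey = %s, predator = %s cells/ml\n",
                last$day, .fmtNum(last$prey), .fmtNum(last$predator)))
  }
})

setMethod("show", "ObservedSeries", function(object) {
  cts <- object@counts
  cat(sprintf("ObservedSeries: %d days x %d replicates\n",
              length(unique(cts$day)), length(unique(cts$replicate))))
})

setMethod("show", "EquilibriumBand", function(object) {
  cat(sprintf("EquilibriumBand [%s]: %s - %s cells/ml (days %d-%d)\n",
              object@species, .fmtNum(object@low), .fmtNum(object@high),
              object@fromDay, object@toDay - 1L))
})

setMethod("show", "GrowthCurveData", function(object) {
  cat(sprintf(
    "GrowthCurveData [%s]: %d replicates x %d hours, init P = %s, C = %s\n",
    object@setup, length(unique(object@samples$replicate)),
    length(unique(object@samples$hour)),
    .fmtNum(object@initP), .fmtNum(object@initC)))
})

setMethod("show", "NoiseModel", function(object) {
  cat(sprintf("NoiseModel: lognormal multiplicative, cv = %g, seed = %d\n",
              object@cv, object@seed))
})

setMethod("show", "CalibrationResult", function(object) {
  cat(sprintf("CalibrationResult [%s]: objective = %s (%d evaluations)\n",
              object@stage, .fmtNum(object@objectiveValue),
              object@nEvaluations))
  show(object@params)
  if (length(object@notes))
    cat("  notes:", paste(object@notes, collapse = "; "), "\n")
})

setMethod("show", "TransientMetrics", function(object) {
  cat("TransientMetrics\n")
  per <- object@perSpecies
  for (i in seq_len(nrow(per))) {
    rec <- if (is.na(per$recoveryTime[i])) {
      if (per$recoveryCensored[i]) "censored" else "undefined"
    } else paste0(per$recoveryTime[i], " d")
    resp <- if (is.na(per$responseTime[i])) "undefined"
            else paste0(per$responseTime[i], " d")
    cat(sprintf("  %-8s response %s, recovery %s\n", per$species[i],
                resp, rec))
  }
  cat(sprintf("  covariance before %s, during/after %s\n",
              .fmtNum(object@covBefore),
              if (is.na(object@covDuringAfter)) "NA"
              else .fmtNum(object@covDuringAfter)))
})

setMethod("show", "SweepSpec", function(object) {
  cat(sprintf("SweepSpec: %s over %s (%d days each)\n", object@variable,
              paste(.fmtNum(range(object@values)), collapse = " - "),
              object@nDays))
})

setMethod("show", "SweepResult", function(object) {
  cat(sprintf("SweepResult: %s, %d values\n", object@spec@variable,
              length(object@spec@values)))
  print(object@table)
})
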