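# Shared fixtures: everything is generated in code at test time.

# the calibrated microcosm parameter set used throughout
microParams <- function(...) modelParameters(...)

# protocol inocula
controlInit <- function() populationState(3.6e7, 4.2e4)
pulseInit <- function() populationState(4e6, 4e3)

# a short deterministic control run, daily series only
controlDaily <- function(nDays = 10, params = microParams(),
                         init = controlInit()) {
  dailySeries(simulateMicrocosm(params,
                                buildSchedule(controlRegime(), nDays),
                                init, nDays))
}

# recovery days with censored runs ranked above any finite time
recoveryRank <- function(tab) {
  ifelse(tab$censored, Inf, tab$recoveryDays)
}
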