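## Run configuration: a YAML file describing parameters, regime, inoculum,
## horizon, metric options, calibration options and an optional sweep.
## Every defaulted field is filled in on load so the echoed config in the
## run manifest fully reconstructs the run.

.configDefaults <- function() {
  list(
    parameters = list(r_P = 0.094, r_C = 0.012, K_P = 4.9e8,
                      c_P = 3.5e-6, c_C = 1.4e-11,
                      step_minutes = 7.5, steps_per_day = 192),
    regime = list(kind = "control", baseline_fold = 10,
                  disturbance_fold = NULL, start_day = NULL,
                  duration_days = NULL),
    init = list(prey = 3.6e7, predator = 4.2e4),
    n_days = 40,
    metrics = list(band_from = 7, cov_scaling = "max"),
    calibration = list(half_width = 0.2, n_samples = 500, seed = 1,
                       exponent = 4, freeze = list()),
    sweep = NULL,
    fixtures = list(n_days = 21, n_replicates = 3, cv = 0.1, seed = 1),
    output_dir = "presspulse-out"
  )
}

.mergeConfig <- function(defaults, user) {
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && is.list(user[[k]]))
      defaults[[k]] <- .mergeConfig(defaults[[k]], user[[k]])
    else defaults[[k]] <- user[[k]]
  }
  defaults
}

#' Load and validate a run configuration
#'
#' Reads a YAML run configuration, fills every omitted field with its
#' documented default, and validates the result; the returned list is
#' complete, so echoing it reconstructs the run exactly.
#'
#' @param path YAML file, or a list already in config shape
#' @return a validated config list
#' @examples
#' cfg <- readRunConfig(system.file("extdata", "configs", "pulse.yaml",
#'                                  package = "presspulse"))
#' cfg$regime$disturbance_fold
#' @export
readRunConfig <- function(path) {
  user <- if (is.character(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    yaml::read_yaml(path)
  } else if (is.list(path)) path
  else stop("path must be a file path or a list")
  cfg <- .mergeConfig(.configDefaults(), user)

  kind <- cfg$regime$kind
  if (!kind %in% c("control", "press", "pulse"))
    stop("config field regime.kind must be control, press or pulse")
  if (kind != "control") {
    for (f in c("disturbance_fold", "start_day"))
      if (is.null(cfg$regime[[f]]))
        stop("config field regime.", f, " is required for a ", kind,
             " regime")
    if (kind == "pulse") cfg$regime$duration_days <- 1
    if (is.null(cfg$regime$duration_days))
      stop("config field regime.duration_days is required for a press regime")
  }
  for (f in c("r_P", "r_C", "K_P", "c_P", "c_C"))
    if (is.null(cfg$parameters[[f]]) || !is.numeric(cfg$parameters[[f]]))
      stop("config field parameters.", f, " must be a number")
  if (!is.numeric(cfg$n_days) || cfg$n_days < 1)
    stop("config field n_days must be >= 1")
  if (!is.null(cfg$sweep)) {
    if (is.null(cfg$sweep$variable))
      stop("config field sweep.variable is required")
    if (!is.null(cfg$sweep$values) && length(cfg$sweep$values) == 0)
      stop("config field sweep.values must be non-empty")
  }
  cfg
}

.paramsFromConfig <- function(cfg) {
  p <- cfg$parameters
  modelParameters(rP = p$r_P, rC = p$r_C, KP = p$K_P, cP = p$c_P,
                  cC = p$c_C, stepMinutes = p$step_minutes,
                  stepsPerDay = as.integer(p$steps_per_day))
}

.regimeFromConfig <- function(cfg) {
  r <- cfg$regime
  if (r$kind == "control") controlRegime(r$baseline_fold)
  else disturbanceRegime(r$kind, r$baseline_fold, r$disturbance_fold,
                         r$start_day, r$duration_days)
}

.initFromConfig <- function(cfg) {
  populationState(cfg$init$prey, cfg$init$predator)
}

.sweepFromConfig <- function(cfg) {
  s <- cfg$sweep
  sweepSpec(variable = s$variable,
            values = if (is.null(s$values)) NULL else as.numeric(s$values),
            baseParams = .paramsFromConfig(cfg),
            baseRegime = .regimeFromConfig(cfg),
            init = .initFromConfig(cfg),
            nDays = if (is.null(s$n_days)) NULL else as.integer(s$n_days))
}
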