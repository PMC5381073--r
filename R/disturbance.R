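#' Convert between dilution folds and per-day dilution rates
#'
#' A fold-f daily transfer retains fraction 1/f of the culture, so the
#' equivalent per-day mortality rate is \code{d = 1 - 1/f}: the control's
#' tenfold dilution corresponds to d = 0.9 per day.
#'
#' @param fold dilution fold(s), >= 1
#' @param rate per-day dilution rate(s) in \code{[0, 1)}
#' @return `foldToRate()` the rate(s); `rateToFold()` the fold(s)
#' @examples
#' foldToRate(10)    # 0.9
#' foldToRate(c(40, 2500))
#' rateToFold(0.9)   # 10
#' @export
foldToRate <- function(fold) {
  if (any(!is.finite(fold)) || any(fold < 1))
    stop("dilution fold must be >= 1")
  1 - 1 / fold
}

#' @rdname foldToRate
#' @export
rateToFold <- function(rate) {
  if (any(!is.finite(rate)) || any(rate < 0) || any(rate >= 1))
    stop("dilution rate must lie in [0, 1)")
  1 / (1 - rate)
}

#' Construct disturbance regimes
#'
#' `disturbanceRegime()` is the general constructor;
#' `controlRegime()`, `pressRegime()` and `pulseRegime()` encode the
#' three experimental treatments with their protocol defaults: tenfold
#' daily dilution throughout (control); 40-fold daily dilution on the 10
#' consecutive days 22-31, normal dilution resuming on day 32 (press); a
#' single 2500-fold dilution on day 15 (pulse).
#'
#' "Disturbance on day k" means the dilution event at the start of day k
#' uses the disturbed fold; the disturbed days are
#' \code{startDay, ..., startDay + durationDays - 1}.
#'
#' @param kind \code{"control"}, \code{"press"} or \code{"pulse"}
#' @param baselineFold daily fold under normal operation
#' @param disturbanceFold fold on disturbed days
#' @param startDay first disturbed day
#' @param durationDays number of disturbed days (1 for pulse)
#' @return a [DisturbanceRegime-class]
#' @examples
#' pressRegime()
#' pulseRegime(disturbanceFold = 1e4)
#' @export
disturbanceRegime <- function(kind = c("control", "press", "pulse"),
                              baselineFold = 10,
                              disturbanceFold = baselineFold,
                              startDay = NA, durationDays = NA) {
  kind <- match.arg(kind)
  if (kind == "control") {
    startDay <- NA_integer_
    durationDays <- 0L
    disturbanceFold <- baselineFold
  }
  new("DisturbanceRegime", kind = kind,
      baselineFold = as.numeric(baselineFold),
      disturbanceFold = as.numeric(disturbanceFold),
      startDay = as.integer(startDay),
      durationDays = as.integer(durationDays))
}

#' @rdname disturbanceRegime
#' @export
controlRegime <- function(baselineFold = 10) {
  disturbanceRegime("control", baselineFold = baselineFold)
}

#' @rdname disturbanceRegime
#' @export
pressRegime <- function(baselineFold = 10, disturbanceFold = 40,
                        startDay = 22, durationDays = 10) {
  disturbanceRegime("press", baselineFold, disturbanceFold,
                    startDay, durationDays)
}

#' @rdname disturbanceRegime
#' @export
pulseRegime <- function(baselineFold = 10, disturbanceFold = 2500,
                        startDay = 15) {
  disturbanceRegime("pulse", baselineFold, disturbanceFold,
                    startDay, durationDays = 1)
}

#' Ratio of disturbed to baseline dilution fold
#'
#' The "n times increased dilution" figure of a regime: 40-fold press
#' over a 10-fold baseline is a 4-fold increase, a 2500-fold pulse a
#' 250-fold increase.
#'
#' @param regime [DisturbanceRegime-class]
#' @return \code{disturbanceFold / baselineFold}
#' @examples
#' foldRatio(pressRegime())  # 4
#' foldRatio(pulseRegime())  # 250
#' @export
foldRatio <- function(regime) {
  stopifnot(is(regime, "DisturbanceRegime"))
  regime@disturbanceFold / regime@baselineFold
}

#' First day after a disturbance
#'
#' The day whose dilution event is back at the baseline fold: for the
#' default press regime (days 22-31 disturbed) this is day 32; for the
#' default pulse (day 15) it is day 16. Recovery times are measured from
#' this day. NA for control regimes.
#'
#' @param regime [DisturbanceRegime-class]
#' @return integer day, or NA
#' @export
disturbanceEnd <- function(regime) {
  stopifnot(is(regime, "DisturbanceRegime"))
  if (regime@kind == "control") return(NA_integer_)
  regime@startDay + regime@durationDays
}

#' Build the per-day dilution schedule of a regime
#'
#' Every day carries the baseline fold except the disturbed days
#' \code{startDay ... startDay + durationDays - 1}, which carry the
#' disturbance fold.
#'
#' @param regime [DisturbanceRegime-class]
#' @param nDays schedule length, days; disturbed regimes require
#'   \code{startDay + durationDays <= nDays} so at least one
#'   post-disturbance day exists
#' @return a [DilutionSchedule-class]
#' @examples
#' sched <- buildSchedule(pressRegime(), 40)
#' table(scheduleFolds(sched))
#' @export
buildSchedule <- function(regime, nDays) {
  stopifnot(is(regime, "DisturbanceRegime"))
  nDays <- as.integer(nDays)
  if (nDays < 1L) stop("nDays must be >= 1")
  folds <- rep(regime@baselineFold, nDays)
  if (regime@kind != "control") {
    if (regime@startDay < 1L || regime@startDay + regime@durationDays > nDays)
      stop(sprintf(
        "disturbance window (days %d-%d) does not fit in %d days",
        regime@startDay, regime@startDay + regime@durationDays - 1L, nDays))
    idx <- regime@startDay:(regime@startDay + regime@durationDays - 1L)
    folds[idx] <- regime@disturbanceFold
  }
  new("DilutionSchedule", folds = folds, rates = foldToRate(folds))
}
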