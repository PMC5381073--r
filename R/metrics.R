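#' Nash-Sutcliffe efficiency
#'
#' Model-fit metric \eqn{E = 1 - \sum(o_i - p_i)^2 / \sum(o_i -
#' \bar{o})^2}. E = 1 is a perfect fit; E = 0 means the model predicts no
#' better than the mean of the observations; negative values mean the
#' observation mean is the better predictor. E is unbounded below.
#'
#' @param predicted model series
#' @param observed observed series, same length and time points
#' @return the efficiency E (scalar, \code{<= 1})
#' @examples
#' nashSutcliffe(c(1, 2, 5), c(1, 2, 3))  # -1
#' @export
nashSutcliffe <- function(predicted, observed) {
  if (length(predicted) != length(observed))
    stop("predicted and observed must have equal length")
  if (length(observed) < 2L)
    stop("need at least 2 points")
  if (any(!is.finite(predicted)) || any(!is.finite(observed)))
    stop("series must be finite")
  sst <- sum((observed - mean(observed))^2)
  if (sst == 0)
    stop("observed series has zero variance; E is undefined")
  1 - sum((observed - predicted)^2) / sst
}

#' Equilibrium band of a daily series
#'
#' The min-max envelope of the per-day values over the window
#' \code{[fromDay, toDay - 1]} -- by convention "from day 7 until
#' disturbance start". For observed data pass the replicate-mean series.
#'
#' \code{minHalfWidth} optionally expands the band to at least that
#' relative half-width around its midpoint. A deterministic trajectory
#' settled on its equilibrium has essentially zero day-to-day range, and
#' a zero-width band makes any return-to-band time an asymptotic
#' non-event; simulation sweeps therefore use a small minimum width
#' (replicated experimental data never need this -- replicate scatter
#' gives the band natural width).
#'
#' @param days integer day labels, parallel to \code{values}
#' @param values daily abundances, cells/ml
#' @param fromDay first day of the window
#' @param toDay first day past the window (exclusive)
#' @param species label stored in the result
#' @param minHalfWidth minimum band half-width as a fraction of the band
#'   midpoint (default 0: the raw min-max range)
#' @return an [EquilibriumBand-class]
#' @examples
#' equilibriumBand(7:14, c(10, 12, 11, 9, 10, 12, 11, 10), 7, 15)
#' @export
equilibriumBand <- function(days, values, fromDay, toDay, species = "",
                            minHalfWidth = 0) {
  stopifnot(length(days) == length(values), minHalfWidth >= 0)
  if (fromDay >= toDay) stop("need fromDay < toDay")
  sel <- days >= fromDay & days < toDay
  if (!any(sel)) stop("empty equilibrium window")
  lo <- min(values[sel])
  hi <- max(values[sel])
  centre <- (lo + hi) / 2
  if (centre > 0 && (hi - lo) / 2 < minHalfWidth * centre) {
    lo <- centre * (1 - minHalfWidth)
    hi <- centre * (1 + minHalfWidth)
  }
  new("EquilibriumBand", species = species, low = lo, high = hi,
      fromDay = as.integer(fromDay), toDay = as.integer(toDay))
}

#' Response time to a disturbance
#'
#' Days between the start of the disturbance and the first day on which
#' the population leaves its equilibrium band. A population already
#' outside the band on the start day has response time 0. Returns NA
#' (undefined) if the series never leaves the band over the available
#' horizon.
#'
#' @param days,values the daily series (model series or replicate means)
#' @param band [EquilibriumBand-class] from the pre-disturbance window
#' @param disturbanceStart first disturbed day; must not precede the end
#'   of the band window
#' @return integer days >= 0, or NA
#' @examples
#' b <- equilibriumBand(7:14, rep(c(9, 12), 4), 7, 15)
#' responseTime(15:20, c(10, 11, 8, 7, 7, 8), b, 15)  # 2
#' @export
responseTime <- function(days, values, band, disturbanceStart) {
  stopifnot(is(band, "EquilibriumBand"), length(days) == length(values))
  if (band@toDay > disturbanceStart)
    stop("band window overlaps the post-disturbance scan")
  sel <- which(days >= disturbanceStart)
  if (!length(sel)) stop("series does not cover the disturbance start")
  out <- values[sel] < band@low | values[sel] > band@high
  if (!any(out)) return(NA_integer_)
  as.integer(days[sel[which(out)[1L]]] - disturbanceStart)
}

#' Recovery time after a disturbance
#'
#' Days from the end of the disturbance (the first day diluted at the
#' baseline fold again) to the population's return to its
#' pre-disturbance equilibrium band. Two return criteria are available:
#' \describe{
#'   \item{\code{"inside"}}{(default) the first day whose value lies
#'     inside \code{[low, high]}.}
#'   \item{\code{"crossing"}}{the first day the value is at or beyond
#'     the band from the side it was displaced to -- a population below
#'     the band has returned once it reaches \code{low}, one above once
#'     it drops to \code{high}. With daily sampling, a population
#'     regrowing several-fold per day can step clean across a band
#'     narrower than one day's growth; \code{"inside"} then measures
#'     the decay of the overshoot rather than the return, so sweeps use
#'     \code{"crossing"}.}
#' }
#' If no return occurs before the series ends the value is NA and
#' carries \code{attr(, "censored") = TRUE} with the scan horizon -- a
#' censored recovery is reported as censored, never extrapolated.
#'
#' @param days,values the daily series
#' @param band [EquilibriumBand-class]
#' @param disturbanceEnd first post-disturbance day
#' @param criterion \code{"inside"} or \code{"crossing"}
#' @return integer days >= 0, or NA with attributes \code{censored} and
#'   \code{horizon}
#' @examples
#' b <- equilibriumBand(7:14, rep(c(9, 12), 4), 7, 15)
#' recoveryTime(32:38, c(5, 6, 7, 8, 10, 11, 11), b, 32)  # 4
#' @export
recoveryTime <- function(days, values, band, disturbanceEnd,
                         criterion = c("inside", "crossing")) {
  stopifnot(is(band, "EquilibriumBand"), length(days) == length(values))
  criterion <- match.arg(criterion)
  sel <- which(days >= disturbanceEnd)
  if (!length(sel)) stop("series does not cover the disturbance end")
  v <- values[sel]
  back <- if (criterion == "inside") {
    v >= band@low & v <= band@high
  } else {
    if (v[1L] < band@low) v >= band@low
    else if (v[1L] > band@high) v <= band@high
    else rep(TRUE, length(v))  # already in band at the end day
  }
  if (!any(back)) {
    out <- NA_integer_
    attr(out, "censored") <- TRUE
    attr(out, "horizon") <- max(days[sel])
    return(out)
  }
  as.integer(days[sel[which(back)[1L]]] - disturbanceEnd)
}

#' Deviation time between model and data
#'
#' D_T = response (or recovery) time of the model minus that of the
#' replicate-averaged data. Negative D_T means the model responds (or
#' recovers) earlier than the data: a model responding on day +1 when
#' the data respond on day +4 gives D_T = -3. Each side's equilibrium
#' band is computed from its own series over the same pre-disturbance
#' window.
#'
#' @param modelDays,modelValues daily model series
#' @param observed [ObservedSeries-class]
#' @param species \code{"prey"} or \code{"predator"} (which observed
#'   column to use)
#' @param bandFrom,bandTo pre-disturbance band window (\code{bandTo}
#'   exclusive)
#' @param eventDay disturbance start (type "response") or first
#'   post-disturbance day (type "recovery")
#' @param type \code{"response"} or \code{"recovery"}
#' @return signed days, or NA (flagged undefined) if either time is
#'   undefined
#' @export
deviationTime <- function(modelDays, modelValues, observed, species,
                          bandFrom, bandTo, eventDay,
                          type = c("response", "recovery")) {
  stopifnot(is(observed, "ObservedSeries"),
            species %in% c("prey", "predator"))
  type <- match.arg(type)
  means <- replicateMeans(observed)
  obsValues <- means[[species]]
  obsDays <- means$day
  timeOf <- function(days, values) {
    band <- equilibriumBand(days, values, bandFrom, bandTo, species)
    if (type == "response") responseTime(days, values, band, eventDay)
    else recoveryTime(days, values, band, eventDay)
  }
  tm <- timeOf(modelDays, modelValues)
  td <- timeOf(obsDays, obsValues)
  if (is.na(tm) || is.na(td)) {
    out <- NA_integer_
    attr(out, "undefined") <- TRUE
    return(out)
  }
  as.integer(tm) - as.integer(td)
}

#' Windowed prey-predator covariance (prey-release diagnostic)
#'
#' Sample covariance of the prey and predator daily series over a window
#' of days, after rescaling each full series to a common dimensionless
#' scale (default: divide by its maximum over the whole experiment; raw
#' cells/ml covariances would be O(1e10)). A covariance that is more
#' negative during/after a disturbance than before it indicates prey
#' release: the prey increases because the predator has been suppressed.
#'
#' @param prey,predator daily abundance series over the full experiment
#' @param days day labels, parallel to both series
#' @param fromDay,toDay window, both inclusive
#' @param scaling \code{"max"} (default), \code{"zscore"},
#'   \code{"log10"} or \code{"none"}; applied to each full series before
#'   windowing
#' @return dimensionless sample covariance; 0 when either series is
#'   constant in the window
#' @examples
#' preyReleaseCovariance(c(0.2, 0.8), c(0.9, 0.1), days = 1:2,
#'                       fromDay = 1, toDay = 2, scaling = "none")  # -0.24
#' @export
preyReleaseCovariance <- function(prey, predator, days, fromDay, toDay,
                                  scaling = c("max", "zscore", "log10",
                                              "none")) {
  scaling <- match.arg(scaling)
  stopifnot(length(prey) == length(days), length(predator) == length(days))
  rescale <- function(x) {
    switch(scaling,
      max = if (max(x) > 0) x / max(x) else x,
      zscore = if (stats::sd(x) > 0) (x - mean(x)) / stats::sd(x) else x * 0,
      log10 = log10(pmax(x, 1)),
      none = x
    )
  }
  p <- rescale(prey)
  c_ <- rescale(predator)
  sel <- days >= fromDay & days <= toDay
  if (sum(sel) < 2L) stop("covariance window must contain >= 2 days")
  stats::cov(p[sel], c_[sel])
}
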