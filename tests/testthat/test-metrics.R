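test_that("Nash-Sutcliffe efficiency satisfies its defining anchors", {
  obs <- c(1, 2, 3)
  expect_identical(nashSutcliffe(obs, obs), 1)
  # mean predictor scores exactly zero
  expect_equal(nashSutcliffe(rep(mean(obs), 3), obs), 0)
  # hand evaluation: SSE = 4, SST = 2
  expect_equal(nashSutcliffe(c(1, 2, 5), obs), -1)
  # invariant under a common shift of both series
  pred <- c(0.8, 2.3, 2.9)
  expect_equal(nashSutcliffe(pred + 17, obs + 17),
               nashSutcliffe(pred, obs))
  # E = 1 iff identical
  expect_lt(nashSutcliffe(pred, obs), 1)
  expect_error(nashSutcliffe(c(1, 2), c(5, 5)), "zero variance")
  expect_error(nashSutcliffe(1, 1), "at least 2")
})

test_that("equilibrium band is the min-max envelope of the window", {
  b <- equilibriumBand(rep(1, 4), c(5, 5, 5, 5), 1, 2)
  expect_identical(unname(bandLimits(b)), c(5, 5))

  b <- equilibriumBand(7:14, c(10, 12, 11, 9, 10, 12, 11, 10), 7, 15)
  expect_identical(unname(bandLimits(b)), c(9, 12))
  # toDay is exclusive
  b2 <- equilibriumBand(7:14, c(10, 12, 11, 9, 10, 12, 11, 100), 7, 14)
  expect_identical(b2@high, 12)
  expect_error(equilibriumBand(1:3, 1:3, 5, 9), "empty")
  expect_error(equilibriumBand(1:3, 1:3, 3, 3), "fromDay < toDay")

  # minimum half-width expands a degenerate band around its midpoint
  b3 <- equilibriumBand(1:4, rep(100, 4), 1, 5, minHalfWidth = 0.05)
  expect_equal(unname(bandLimits(b3)), c(95, 105))
  # but never narrows a wide one
  b4 <- equilibriumBand(7:14, c(10, 12, 11, 9, 10, 12, 11, 10), 7, 15,
                        minHalfWidth = 0.05)
  expect_identical(unname(bandLimits(b4)), c(9, 12))
})

test_that("response time counts days from disturbance start to band exit", {
  b <- equilibriumBand(7:14, rep(c(9, 12), 4), 7, 15)
  # leaves the band on the start day itself
  expect_identical(responseTime(15:18, c(8, 8, 9, 10), b, 15), 0L)
  # first excursion two days in
  expect_identical(responseTime(15:20, c(10, 11, 8, 7, 7, 8), b, 15), 2L)
  # never leaves: undefined
  expect_true(is.na(responseTime(15:20, rep(10, 6), b, 15)))
  # band window overlapping the scan is a configuration error
  expect_error(responseTime(10:20, rep(10, 11), b, 12), "overlaps")
  # invariant under a constant day relabeling of all inputs
  b2 <- equilibriumBand(107:114, rep(c(9, 12), 4), 107, 115)
  expect_identical(responseTime(115:120, c(10, 11, 8, 7, 7, 8), b2, 115), 2L)
})

test_that("recovery time counts days from disturbance end to band return", {
  b <- equilibriumBand(7:14, rep(c(9, 12), 4), 7, 15)
  # already inside at the end day
  expect_identical(recoveryTime(32:35, c(10, 10, 10, 10), b, 32), 0L)
  # returns inside on day 36
  expect_identical(recoveryTime(32:38, c(5, 6, 7, 8, 10, 11, 11), b, 32), 4L)
  # censoring: no fabricated value past the series end
  rt <- recoveryTime(32:36, c(5, 6, 7, 8, 8.5), b, 32)
  expect_true(is.na(rt))
  expect_true(attr(rt, "censored"))
  expect_identical(attr(rt, "horizon"), 36L)

  # crossing criterion: a series stepping over the band from below has
  # returned at the crossing, not when the overshoot decays
  v <- c(5, 7, 20, 15, 11)
  expect_identical(recoveryTime(32:36, v, b, 32, criterion = "inside"), 4L)
  expect_identical(recoveryTime(32:36, v, b, 32, criterion = "crossing"), 2L)
  # from above
  expect_identical(recoveryTime(32:35, c(20, 14, 11, 10), b, 32,
                                criterion = "crossing"), 2L)
})

test_that("deviation time is model minus replicate-mean data", {
  # synthetic observed: model series shifted k days later must give -k
  days <- 0:30
  model <- c(rep(10, 16), 8, 6, 5, 5, 6, 8, rep(10, 9))  # leaves band day 16
  for (k in c(1, 3)) {
    shifted <- c(rep(10, 16 + k), model[17:(31 - k)])
    obsCounts <- do.call(rbind, lapply(1:3, function(r)
      data.frame(day = days, replicate = r, prey = 1,
                 predator = shifted)))
    obs <- new("ObservedSeries", counts = obsCounts)
    dt <- deviationTime(days, model, obs, "predator",
                        bandFrom = 7, bandTo = 15, eventDay = 15,
                        type = "response")
    expect_identical(dt, -as.integer(k))
  }

  # sign-convention anchor: model responds on day +1, data on day +4
  model2 <- c(rep(10, 15), 10, 5, rep(5, 14))          # leaves day 16 (+1)
  data2 <- c(rep(10, 15), 10, 10, 10, 10, 5, rep(5, 11))  # leaves day 19 (+4)
  obs2 <- new("ObservedSeries",
              counts = data.frame(day = days, replicate = 1, prey = 1,
                                  predator = data2))
  expect_identical(
    deviationTime(days, model2, obs2, "predator", 7, 15, 15, "response"),
    -3L)

  # model identical to observed means: zero deviation
  obs3 <- new("ObservedSeries",
              counts = data.frame(day = days, replicate = 1, prey = 1,
                                  predator = model))
  expect_identical(
    deviationTime(days, model, obs3, "predator", 7, 15, 15, "response"), 0L)

  # either side undefined propagates as flagged NA
  flat <- new("ObservedSeries",
              counts = data.frame(day = days, replicate = 1, prey = 1,
                                  predator = rep(10, 31)))
  dt <- deviationTime(days, model, flat, "predator", 7, 15, 15, "response")
  expect_true(is.na(dt))
  expect_true(attr(dt, "undefined"))
})

test_that("prey-release covariance matches hand computation and contracts", {
  # two-point hand computation, series already on [0, 1] scale
  expect_equal(preyReleaseCovariance(c(0.2, 0.8), c(0.9, 0.1), 1:2, 1, 2,
                                     scaling = "none"), -0.24)
  # symmetric under exchanging the series
  prey <- c(3, 9, 27, 12, 5); pred <- c(9, 7, 2, 4, 8)
  expect_equal(
    preyReleaseCovariance(prey, pred, 1:5, 2, 5),
    preyReleaseCovariance(pred, prey, 1:5, 2, 5))
  # constant predator in the window: exactly zero
  expect_identical(
    preyReleaseCovariance(c(1, 5, 3), c(4, 4, 4), 1:3, 1, 3,
                          scaling = "none"), 0)
  # max scaling divides each series by its own full-experiment maximum
  expect_equal(
    preyReleaseCovariance(prey, pred, 1:5, 1, 5, scaling = "max"),
    stats::cov(prey / 27, pred / 9))
  # bilinear scaling contract: rescaling inputs leaves "max" output alone
  expect_equal(
    preyReleaseCovariance(prey * 1e6, pred * 1e3, 1:5, 1, 5),
    preyReleaseCovariance(prey, pred, 1:5, 1, 5))
  expect_error(preyReleaseCovariance(prey, pred, 1:5, 2, 2), ">= 2 days")
})

test_that("simulated pulse shows increasingly negative covariance (prey release)", {
  tr <- simulateMicrocosm(microParams(), buildSchedule(pulseRegime(), 30),
                          pulseInit())
  d <- dailySeries(tr)
  before <- preyReleaseCovariance(d$prey, d$predator, d$day, 8, 14)
  after <- preyReleaseCovariance(d$prey, d$predator, d$day, 15, 21)
  expect_lt(after, before)
  expect_lt(after, 0)
})
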