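test_that("monthly normalisation pools years and flags undefined months", {
  ## 8 cloud-free March observations across years, 2 of them detections
  dates <- c(as.Date("2017-03-05") + c(0, 5, 10, 15),
             as.Date("2018-03-05") + c(0, 5, 10, 15),
             as.Date("2018-06-01"))
  states <- c(2L, 2L, 1L, 1L, 1L, 1L, 1L, 1L, 3L)
  ms <- monthlySeries(states, dates)
  expect_equal(ms$values[3], 0.25)
  expect_equal(ms$obsCounts[3], 8L)
  expect_equal(ms$detectionCounts[3], 2L)
  expect_true(is.na(ms$values[6]))   # only a cloud observation in June

  expect_true(all(monthlySeries(rep(1L, 12),
                                as.Date("2019-01-01") + 0:11)$values[1] == 0))
  expect_true(all(is.na(monthlySeries(rep(3L, 5),
                                      as.Date("2019-01-01") + 0:4)$values)))
  expect_error(monthlySeries(integer(0), as.Date(character(0))), "empty")
})

test_that("cleaning applies exclusion, isolated-peak, scaling, shoulders, weights", {
  ## fewer than 4 detections in total: pixel excluded, not an error
  expect_true(cleanSeries(msFromCounts(c(3, rep(0, 11)), rep(10, 12)))$excluded)

  ## isolated March peak from one detection between empty months -> zeroed
  det <- c(0, 0, 1, 0, 0, 0, 0, 0, 5, 5, 0, 0)
  cs <- cleanSeries(msFromCounts(det, rep(10, 12)))
  expect_false(cs$excluded)
  expect_equal(cs$values[3], 0)

  ## x10 scaling and value weights; September 0.5 -> 5 with weight 5
  expect_equal(cs$values[9], 5)
  expect_equal(cs$weights[9], 5)

  ## shoulders at -0.15 x max of the scaled series, weight 1
  expect_equal(max(cs$values), 5)
  expect_equal(cs$shoulderValue, -0.75)
  expect_equal(cs$values[8], -0.75)   # month before the run
  expect_equal(cs$values[11], -0.75)  # month after the run
  expect_equal(cs$weights[8], 1)
  expect_equal(cs$weights[11], 1)
  ## zero months keep weight zero
  expect_equal(cs$weights[1], 0)
  expect_setequal(cs$zeroWeightMonths, c(1:7, 12))

  ## 3x replication with 12-month periodicity
  expect_length(cs$values, 36)
  expect_equal(cs$values[1:12], cs$values[13:24])
  expect_equal(cs$weights[13:24], cs$weights[25:36])

  ## a 0.4 March value from >2 detections survives scaling: 4.0, weight 4.0,
  ## and the shoulder then sits at -0.15 * 4
  cs2 <- cleanSeries(msFromCounts(c(0, 0, 4, 0, 0, 0, 0, 0, 0, 0, 0, 0),
                                  rep(10, 12)))
  expect_equal(cs2$values[3], 4)
  expect_equal(cs2$weights[3], 4)
  expect_equal(cs2$shoulderValue, -0.6)
  expect_equal(cs2$values[2], -0.6)
  expect_equal(cs2$values[4], -0.6)
})

test_that("the harmonic fit is exact on representable signals", {
  t <- 1:36
  fit <- fitBloomModel(list(values = 1 + sin(2 * pi * t / 12),
                            weights = rep(1, 36)))
  p <- bloomParams(fit)
  expect_equal(unname(p["bloom0"]), 1, tolerance = 1e-6)
  expect_equal(unname(p["pow0"]), 1, tolerance = 1e-6)
  expect_equal(unname(p["p12"]), 1, tolerance = 1e-6)
  expect_equal(unname(p["p4"]), 0, tolerance = 1e-6)
  expect_equal(unname(p["p6"]), 0, tolerance = 1e-6)
  expect_equal(unname(p["rho12"]), 0, tolerance = 1e-6)
  expect_equal(weightedR2(fit), 1, tolerance = 1e-9)

  ## constant series: degenerate zero-power fit, R2 = 1 by convention
  fc <- fitBloomModel(list(values = rep(2.5, 36), weights = rep(1, 36)))
  expect_equal(unname(bloomParams(fc)["bloom0"]), 2.5, tolerance = 1e-9)
  expect_equal(unname(bloomParams(fc)["pow0"]), 0, tolerance = 1e-9)
  expect_equal(weightedR2(fc), 1)
  expect_equal(unname(sum(bloomParams(fc)[c("p4", "p6", "p12")])), 1)

  expect_error(fitBloomModel(list(values = rep(1, 36),
                                  weights = rep(0, 36))), "weights")
})

test_that("the amplitude/phase parameterisation equals exact linear WLS", {
  mkSignal <- function(t, pars) {
    pars$bloom0 + pars$pow0 * (
      pars$p4 * sin(2 * pi * t / 4 + pars$rho4) +
        pars$p6 * sin(2 * pi * t / 6 + pars$rho6) +
        pars$p12 * sin(2 * pi * t / 12 + pars$rho12))
  }
  set.seed(4)
  t <- 1:36
  for (rep in 1:10) {
    pars <- list(bloom0 = runif(1, -1, 2), pow0 = runif(1, 0.5, 3),
                 p4 = 0, p6 = 0, p12 = 0,
                 rho4 = runif(1, -pi, pi), rho6 = runif(1, -pi, pi),
                 rho12 = runif(1, -pi, pi))
    pr <- runif(3); pr <- pr / sum(pr)
    pars$p4 <- pr[1]; pars$p6 <- pr[2]; pars$p12 <- pr[3]
    y <- mkSignal(t, pars) + rnorm(36, sd = 0.3)
    w <- runif(36, 0.2, 3)
    fit <- fitBloomModel(list(values = y, weights = w))
    ## independent oracle: lm.wfit on the sine/cosine basis
    X <- cbind(1, sin(2 * pi * t / 4), cos(2 * pi * t / 4),
               sin(2 * pi * t / 6), cos(2 * pi * t / 6),
               sin(2 * pi * t / 12), cos(2 * pi * t / 12))
    ref <- stats::lm.wfit(X, y, w)
    expect_equal(fit@fitted, unname(ref$fitted.values), tolerance = 1e-8)
    ## and the nonlinear parameterisation reproduces those fitted values
    back <- mkSignal(t, as.list(bloomParams(fit)))
    expect_equal(back, fit@fitted, tolerance = 1e-8)
    expect_equal(unname(sum(bloomParams(fit)[c("p4", "p6", "p12")])), 1,
                 tolerance = 1e-9)
  }
})

test_that("noisy parameter recovery stays within simulation error", {
  set.seed(7)
  t <- 1:36
  truth <- c(bloom0 = 0.5, pow0 = 2, p12 = 0.7, p6 = 0.3,
             rho12 = 1.0, rho6 = 0.4)
  est <- replicate(100, {
    y <- truth["bloom0"] + truth["pow0"] *
      (truth["p12"] * sin(2 * pi * t / 12 + truth["rho12"]) +
         truth["p6"] * sin(2 * pi * t / 6 + truth["rho6"])) +
      rnorm(36, sd = 0.05)
    p <- bloomParams(fitBloomModel(list(values = y, weights = rep(1, 36))))
    p[c("bloom0", "pow0", "p12", "p6", "rho12", "rho6")]
  })
  m <- rowMeans(est)
  se <- apply(est, 1, sd) / sqrt(ncol(est))
  ## amplitude estimates fold noise (|a + e| >= |a|), an O(sigma^2) upward
  ## bias on pow0 and the p's; allow it on top of the Monte Carlo error
  for (nm in names(truth))
    expect_lt(abs(m[nm] - truth[nm]), 3 * se[nm] + 0.01)
})

test_that("phase shifts translate events without changing power or R2", {
  det <- c(0, 0, 0, 2, 6, 9, 5, 0, 0, 0, 0, 0)
  base <- cleanSeries(msFromCounts(det, rep(10, 12)))
  f0 <- fitBloomModel(base)
  d0 <- reconstructDaily(f0, base$zeroWeightMonths)
  e0 <- extractBloomEvents(d0)
  for (shift in c(2, 5)) {
    detS <- det[((seq_len(12) - 1 - shift) %% 12) + 1]
    csS <- cleanSeries(msFromCounts(detS, rep(10, 12)))
    fS <- fitBloomModel(csS)
    expect_equal(fS@pow0, f0@pow0, tolerance = 1e-6)
    expect_equal(bloomParams(fS)[c("p4", "p6", "p12")],
                 bloomParams(f0)[c("p4", "p6", "p12")], tolerance = 1e-6)
    expect_equal(weightedR2(fS), weightedR2(f0), tolerance = 1e-9)
    eS <- extractBloomEvents(reconstructDaily(fS, csS$zeroWeightMonths))
    expect_equal(nrow(eS), nrow(e0))
    dayShift <- shift * 365 / 12
    expect_lt(circDist(eS$peak_day[1], (e0$peak_day[1] + dayShift - 1) %%
                         365 + 1), 2)
  }
})

test_that("daily reconstruction clamps, zeroes and peaks where it should", {
  t <- 1:36
  fit <- fitBloomModel(list(values = 1 + sin(2 * pi * t / 12),
                            weights = rep(1, 36)))
  daily <- reconstructDaily(fit)
  ## the sine peaks at t = 3; month 3's centre maps to day (3-0.5)*365/12+0.5
  expect_equal(which.max(daily), round((3 - 0.5) * 365 / 12 + 0.5))
  expect_true(all(daily >= 0))
  expect_equal(reconstructDaily(fit, 1:12), rep(0, 365))
  ## zeroed months are exactly the equal-length month windows
  d2 <- reconstructDaily(fit, 3)
  expect_true(all(d2[62:91] == 0))
})

test_that("event extraction finds bumps, plateaus and nothing in silence", {
  expect_equal(nrow(extractBloomEvents(rep(0, 365))), 0)

  bump <- pmax(0, dnorm(1:365, 180, 20) * 100 - 0.2)
  ev <- extractBloomEvents(bump)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$peak_day, 180)
  expect_lt(ev$start_day, 180)
  expect_gt(ev$end_day, 180)

  ## two well-separated lobes: brute-force count is two
  lobes <- pmax(0, dnorm(1:365, 100, 15) * 80 - 0.1) +
    pmax(0, dnorm(1:365, 280, 15) * 80 - 0.1)
  ev2 <- extractBloomEvents(lobes)
  expect_equal(nrow(ev2), 2)
  expect_equal(ev2$peak_day, c(100, 280))

  ## plateau maxima report their first day
  plat <- rep(0, 365); plat[100:110] <- 5; plat[99] <- 2; plat[111] <- 2
  expect_equal(extractBloomEvents(plat)$peak_day, 100)

  ## events may straddle the year boundary
  wrap <- pmax(0, dnorm(circDist(1:365, 5), 0, 15) * 80 - 0.1)
  evw <- extractBloomEvents(wrap)
  expect_equal(nrow(evw), 1)
  expect_equal(evw$peak_day, 5)
  expect_gt(evw$start_day, evw$end_day)  # circular span
})

test_that("any fit of the three-harmonic family has at most three peaks", {
  set.seed(13)
  for (i in 1:25) {
    pr <- runif(3); pr <- pr / sum(pr)
    fit <- new("BloomFit", bloom0 = runif(1, -1, 1), pow0 = runif(1, 0, 3),
               p4 = pr[1], p6 = pr[2], p12 = pr[3],
               rho4 = runif(1, -pi, pi), rho6 = runif(1, -pi, pi),
               rho12 = runif(1, -pi, pi), weightedR2 = 1,
               fitted = numeric(36), nRep = 3L)
    ev <- extractBloomEvents(reconstructDaily(fit))
    expect_lte(nrow(ev), 3)
  }
})

test_that("the per-pixel wrapper recovers truth phenology end to end", {
  w <- onePixelWorld(c(60, 250), durationDays = 60, seed = 31)
  obs <- simulateObservations(w, oneYearDates(), pDetect = 0.9,
                              cloudProb = 0, seed = 32)
  res <- fitPixelPhenology(obsStates(obs)[1, 1, ], oneYearDates())
  expect_equal(nrow(res$events), 2)
  expect_lt(circDist(res$events$peak_day[1], 60), 8)
  expect_lt(circDist(res$events$peak_day[2], 250), 8)
  ## excluded pixel: almost no detections
  resX <- fitPixelPhenology(c(2L, rep(1L, 40)),
                            as.Date("2018-01-01") + 0:40)
  expect_null(resX)
})
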