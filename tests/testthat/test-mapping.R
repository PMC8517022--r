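test_that("predictions spatialise positionally onto the coarse grid", {
  r <- spatializePredictions(c(1, 0, 0, 1), c(2, 2))
  expect_equal(r, matrix(c(1, 0, 0, 1), 2, 2, byrow = TRUE))
  expect_equal(spatializePredictions(rep(0, 6400), c(80, 80)),
               matrix(0L, 80, 80))
  expect_error(spatializePredictions(rep(0, 5), c(2, 2)), "expected 4")
})

test_that("daily state accumulation applies precedence and replicate merging", {
  p1 <- matrix(c(1L, 0L, 1L, 0L), 2, 2)
  cf1 <- matrix(c(0, 0, 1, 1), 2, 2)      # cells [1,2] and [2,2] clouded
  obs <- accumulateDailyStates(list(p1), list(cf1),
                               as.Date("2019-02-01"),
                               studyDates = as.Date("2019-02-01") + 0:1)
  st <- obsStates(obs)
  expect_equal(st[1, 1, 1], 2L)  # detected
  expect_equal(st[2, 1, 1], 1L)  # clear
  expect_equal(st[1, 2, 1], 3L)  # cloud overrides the presence flag
  expect_equal(st[2, 2, 1], 3L)
  expect_true(all(st[, , 2] == 0L))  # no scene that day -> missing

  ## same-day replicates: OR on detection, AND on cloud
  p2 <- matrix(c(0L, 1L, 1L, 0L), 2, 2)
  cf2 <- matrix(0, 2, 2)
  obs2 <- accumulateDailyStates(list(p1, p2), list(cf1, cf2),
                                rep(as.Date("2019-02-01"), 2))
  st2 <- obsStates(obs2)
  expect_equal(st2[2, 1, 1], 2L)           # detected in the second replicate
  expect_equal(st2[1, 2, 1], 2L)           # clear in one replicate: not cloud
  expect_equal(st2[2, 2, 1], 1L)

  expect_error(accumulateDailyStates(list(p1), list(cf1[1, , drop = FALSE]),
                                     as.Date("2019-02-01")), "share")
})

test_that("simulated observations round-trip through the accumulator", {
  w <- onePixelWorld(100, seed = 6)
  dates <- seq(as.Date("2018-01-01"), by = "5 days", length.out = 73)
  obs <- simulateObservations(w, dates, pDetect = 0.9, cloudProb = 0.2,
                              seed = 8)
  st <- obsStates(obs)
  presenceList <- lapply(seq_along(dates), function(i)
    matrix(as.integer(st[, , i] == 2L), 1, 1))
  cloudList <- lapply(seq_along(dates), function(i)
    matrix(as.numeric(st[, , i] == 3L), 1, 1))
  acc <- accumulateDailyStates(presenceList, cloudList, dates,
                               studyDates = dates)
  expect_identical(tabulate(obsStates(acc) + 1L, 4),
                   tabulate(st + 1L, 4))
})

test_that("frequency maps follow the detection-floor and undefined rules", {
  mk <- function(det, clear, cloud, missing) {
    states <- c(rep(2L, det), rep(1L, clear), rep(3L, cloud),
                rep(0L, missing))
    new("ObservationSeries",
        states = array(states, c(1, 1, length(states))),
        dates = as.Date("2019-01-01") + seq_along(states) - 1)
  }
  fm <- frequencyMap(mk(5, 15, 3, 2))
  expect_equal(frequencyPct(fm)[1, 1], 25)
  cnt <- detectionCounts(fm)
  expect_equal(cnt$detected[1, 1] + cnt$clear[1, 1] + cnt$cloud[1, 1] +
                 cnt$missing[1, 1], 25)

  ## fewer than 4 detections -> frequency forced to zero
  expect_equal(frequencyPct(frequencyMap(mk(3, 17, 0, 0)))[1, 1], 0)
  ## never cloud-free -> undefined
  expect_true(is.na(frequencyPct(frequencyMap(mk(0, 0, 10, 0)))[1, 1]))
  expect_true(is.na(summaryStats(frequencyMap(mk(0, 0, 10, 0)))$medianFrequency))

  ## monotone: an extra detected date never lowers the frequency
  f1 <- frequencyPct(frequencyMap(mk(6, 14, 0, 0)))[1, 1]
  f2 <- frequencyPct(frequencyMap(mk(7, 14, 0, 0)))[1, 1]
  expect_gte(f2, f1)
})

test_that("state counts are conserved on every pixel of a simulated grid", {
  w <- tinyWorld(rows = 6, cols = 6, px = 16, seed = 12)
  dates <- seq(as.Date("2017-01-01"), by = "10 days", length.out = 50)
  obs <- simulateObservations(w, dates, seed = 3)
  fm <- frequencyMap(obs)
  cnt <- detectionCounts(fm)
  tot <- cnt$detected + cnt$clear + cnt$cloud + cnt$missing
  expect_true(all(tot == length(dates)))
})
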