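test_that("world generation is deterministic and respects degenerate configs", {
  cfg <- worldConfig(gridRows = 15, gridCols = 15, patchPixels = 16, seed = 7)
  w1 <- generateWorld(cfg)
  w2 <- generateWorld(cfg)
  expect_identical(presence(w1), presence(w2))
  expect_identical(phenologyTruth(w1), phenologyTruth(w2))
  expect_identical(covariates(w1), covariates(w2))

  w0 <- generateWorld(worldConfig(gridRows = 10, gridCols = 10,
                                  nPopulations = 0, seed = 1))
  expect_false(any(presence(w0)))
  expect_identical(nrow(phenologyTruth(w0)), 0L)

  expect_error(worldConfig(gridRows = 0), "positive")
  expect_error(worldConfig(cloudProb = 1.5), "\\[0, 1\\]")
})

test_that("with a null covariate link the presence count is binomial", {
  w <- generateWorld(worldConfig(
    gridRows = 50, gridCols = 50, nPopulations = 1,
    backgroundFraction = 0.1, twoPeakFraction = 0,
    covariateLink = c(elevation = 0, slope = 0, treecover = 0), seed = 42))
  band <- stats::qbinom(c(0.005, 0.995), 2500, 0.1)
  n <- sum(presence(w))
  expect_gte(n, band[1])
  expect_lte(n, band[2])
  ## one truth row per presence pixel here (twoPeakFraction = 0)
  expect_identical(nrow(phenologyTruth(w)), n)
})

test_that("truth bloom intensity is a wrapped Gaussian bump", {
  expect_equal(bloomIntensity(100, 100, 80, 0.9), 0.9)
  ## symmetric, circular across the year boundary
  expect_equal(bloomIntensity(360, 5, 40, 1), bloomIntensity(15, 5, 40, 1))
  ## at peak +/- duration/2 the intensity is exp(-2) of the amplitude
  expect_equal(bloomIntensity(140, 100, 80, 1), exp(-2))
})

test_that("rendered scenes carry the magenta signature and cloud flags", {
  w0 <- generateWorld(worldConfig(gridRows = 4, gridCols = 4,
                                  patchPixels = 16, nPopulations = 0,
                                  seed = 2))
  sc <- renderScene(w0, 50, seed = 1, cloudProb = 0, noiseSd = 0,
                    nSoilPatches = 0)
  b <- sceneBands(sc)
  expect_equal(mean(b$green), 1200)
  expect_equal(mean(b$red), 700)
  expect_true(all(b$red <= 10000 & b$red >= 0))

  w <- onePixelWorld(100, seed = 4, patchPixels = 32)
  sc <- renderScene(w, 100, seed = 1, cloudProb = 0, noiseSd = 0,
                    nSoilPatches = 0)
  b <- sceneBands(sc)
  ctr <- 16
  contrast <- worldConfigOf(w)$magentaContrast * 0.9
  expect_gte(b$red[ctr, ctr] - b$green[ctr, ctr], contrast - 600)
  expect_gte(b$blue[ctr, ctr] - b$green[ctr, ctr], contrast - 700)

  scAll <- renderScene(w, 1, seed = 1, cloudProb = 1)
  expect_true(all(sceneCloudMask(scAll)))
  expect_equal(cloudFraction(scAll), 1)
})

test_that("observation simulation matches its generating probabilities", {
  w <- onePixelWorld(180, seed = 9)
  expect_error(simulateObservations(w, integer(0)), "empty")

  obs0 <- simulateObservations(w, oneYearDates(), pDetect = 0,
                               cloudProb = 0, seed = 1)
  expect_equal(sum(obsStates(obs0) == 2L), 0)

  dates <- rep(oneYearDates(), length.out = 1000)
  obs <- simulateObservations(w, dates, pDetect = 0.9, cloudProb = 0.3,
                              seed = 2)
  frac <- mean(obsStates(obs) == 3L)
  sd3 <- 3 * sqrt(0.3 * 0.7 / 1000)
  expect_lt(abs(frac - 0.3), sd3)

  ## detections confined to the visible window around the truth peak
  obsd <- simulateObservations(w, oneYearDates(), pDetect = 1,
                               cloudProb = 0, seed = 3)
  detDays <- which(obsStates(obsd)[1, 1, ] == 2L)
  tt <- phenologyTruth(w)
  expect_true(all(circDist(detDays, tt$peak_day) <= tt$duration_days / 2))

  ## state counts per pixel always sum to the number of dates
  counts <- table(factor(obsStates(obs)[1, 1, ], levels = 0:3))
  expect_equal(sum(counts), 1000)
})

test_that("the colour oracle inverts noiseless rendering exactly", {
  w <- tinyWorld(rows = 12, cols = 12, px = 32, seed = 5)
  for (day in c(worldPopulations(w)$peak_day, 80, 200)) {
    vis <- currentlyBlooming(w, day)
    sc8 <- convertSceneTo8Bit(renderScene(w, day, seed = 2, cloudProb = 0,
                                          noiseSd = 0))
    pt <- tileScene(sc8, core = 32, border = 4)
    det <- spatializePredictions(
      vapply(pt, referenceColorDetector, integer(1)), attr(pt, "gridDims"))
    expect_identical(det == 1L, vis)
  }
})
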