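test_that("parameter counts match the closed-form layer sums", {
  cfg <- detectorConfig(nBlocks = 2, filtersPerBlock = c(4, 8),
                        denseUnits = 16, inputSide = 32, seed = 1)
  m <- buildDetector(cfg)
  ## conv: (3*3*in + 1)*out; pooling halves the side per block
  conv1 <- (9 * 4 + 1) * 4
  conv2 <- (9 * 4 + 1) * 8
  flat <- (32 / 4)^2 * 8
  dense1 <- (flat + 1) * 16
  dense2 <- (16 + 1) * 2
  expect_equal(m$nParams, conv1 + conv2 + flat * 16 + 16 + dense2)
  expect_equal(m$nParams, conv1 + conv2 + dense1 + dense2)
  expect_equal(m$nTrainable, m$nParams)

  expect_error(buildDetector(detectorConfig(nBlocks = 5, inputSide = 16)),
               "too small")
})

test_that("the default architecture accepts a 136 x 136 x 4 patch", {
  cfg <- detectorConfig(baseFilters = 4, denseUnits = 10, seed = 1)
  m <- buildDetector(cfg)
  patch <- array(runif(136 * 136 * 4) * 254, c(136, 136, 4))
  pr <- predictPatches(m, list(patch), prob = TRUE)
  expect_true(pr >= 0 && pr <= 1)
  expect_error(predictPatches(m, list(patch[1:64, 1:64, ])), "shape")
})

test_that("flip augmentation is an involution with uniform flip states", {
  p <- array(seq_len(4 * 4 * 2), c(4, 4, 2))
  expect_identical(augmentPatch(augmentPatch(p, TRUE, FALSE), TRUE, FALSE), p)
  expect_identical(augmentPatch(augmentPatch(p, FALSE, TRUE), FALSE, TRUE), p)
  expect_identical(augmentPatch(p, FALSE, FALSE), p)
  marker <- array(0, c(2, 2, 1)); marker[1, 1, 1] <- 1
  set.seed(1)
  states <- replicate(10000, {
    q <- augmentPatch(marker)
    which(q[, , 1] == 1)
  })
  counts <- tabulate(states, 4)
  sd3 <- 3 * sqrt(10000 * 0.25 * 0.75)
  expect_true(all(abs(counts - 2500) < sd3))
})

test_that("class weighting and best-epoch bookkeeping follow the rules", {
  expect_equal(round(classWeightRatio(123071, 35541), 1), 3.5)
  expect_error(classWeightRatio(10, 0), "bloom")
  expect_equal(bestEpoch(c(0.8, 0.9, 0.85)), 2)
  hist <- data.frame(epoch = 1:3, loss = 0,
                     weighted_accuracy = c(0.8, 0.9, 0.85))
  expect_equal(bestEpoch(hist), 2)
})

test_that("training is reproducible and rejects single-class data", {
  n <- 60
  labels <- rep(c(0, 1), length.out = n)
  patches <- lapply(seq_len(n), function(i) separablePatch(labels[i] == 1, i))
  cfg <- detectorConfig(nBlocks = 2, filtersPerBlock = c(4, 8),
                        denseUnits = 8, dropoutRate = 0.2,
                        learningRate = 1e-3, batchSize = 16, epochs = 3,
                        inputSide = 16, seed = 11)
  m <- buildDetector(cfg)
  r1 <- trainDetector(m, patches, labels, cfg)
  r2 <- trainDetector(m, patches, labels, cfg)
  expect_identical(r1$history, r2$history)
  expect_identical(predictPatches(r1$model, patches),
                   predictPatches(r2$model, patches))
  expect_error(trainDetector(m, patches, rep(1, n), cfg), "each class")
})

test_that("prediction thresholds at 0.5 with ties going to presence", {
  cfg <- detectorConfig(nBlocks = 1, filtersPerBlock = 2, denseUnits = 4,
                        inputSide = 8, seed = 1)
  m <- buildDetector(cfg)
  m$dense2$W[] <- 0
  m$dense2$b[] <- 0   # logits (0, 0) -> softmax (0.5, 0.5)
  patch <- array(runif(8 * 8 * 4) * 254, c(8, 8, 4))
  expect_equal(predictPatches(m, list(patch), prob = TRUE), 0.5)
  expect_identical(predictPatches(m, list(patch)), 1L)
  ## pointwise determinism under batch permutation
  batch <- lapply(1:5, function(i) array(runif(8 * 8 * 4) * 254, c(8, 8, 4)))
  p1 <- predictPatches(m, batch)
  p2 <- predictPatches(m, batch[5:1])
  expect_identical(p1, rev(p2))
})

test_that("the colour-rule oracle respects clump size and the core window", {
  green <- array(0, c(24, 24, 4))
  green[, , 2] <- 120; green[, , 1] <- 70; green[, , 3] <- 60
  expect_identical(referenceColorDetector(green), 0L)

  clump <- green
  clump[11:13, 11:13, 1] <- 200
  clump[11:13, 11:13, 3] <- 190
  expect_identical(referenceColorDetector(clump, minClump = 9), 1L)
  expect_identical(referenceColorDetector(clump, minClump = 10), 0L)

  ## a clump wholly inside the 4-pixel border must not flip the label
  borderClump <- green
  borderClump[1:4, 1:24, 1] <- 200
  borderClump[1:4, 1:24, 3] <- 190
  expect_identical(referenceColorDetector(borderClump, minClump = 9), 0L)
})
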