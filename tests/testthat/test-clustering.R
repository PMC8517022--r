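mkEvents <- function(n, pop, pk, cx, cy, seed = 1) {
  set.seed(seed)
  peak <- pk[pop] + round(rnorm(n, 0, 4))
  dur <- 70 + round(rnorm(n, 0, 5))
  list(events = data.frame(pixel_id = seq_len(n),
                           start_day = peak - dur / 2, peak_day = peak,
                           end_day = peak + dur / 2, start_value = 0,
                           peak_value = runif(n, 5, 9), end_value = 0),
       coords = data.frame(pixel_id = seq_len(n),
                           x = cx[pop] + rnorm(n, 0, 30000),
                           y = cy[pop] + rnorm(n, 0, 30000)))
}

test_that("feature rows carry scaled coordinates and one row per event", {
  ev <- data.frame(pixel_id = c(1, 1, 2), start_day = c(10, 200, 50),
                   peak_day = c(30, 230, 80), end_day = c(60, 260, 120),
                   start_value = 0, peak_value = c(5, 4, 7), end_value = 0)
  coords <- data.frame(pixel_id = 1:2, x = c(412345, 51000),
                       y = c(7350000, 7449999))
  rows <- buildFeatureTable(ev, coords)
  expect_equal(nrow(rows), 3)
  expect_equal(rows$x_scaled, c(4, 4, 1))   # 412345 m / 1e5 rounds to 4
  expect_equal(rows$y_scaled[3], 74)
  expect_equal(sum(rows$pixel_id == 1), 2)  # two-peak pixel: two rows

  expect_equal(nrow(buildFeatureTable(ev[0, ], coords)), 0)
  expect_error(buildFeatureTable(transform(ev, pixel_id = 9), coords),
               "coordinates")
})

test_that("features are standardised and K-means is seeded and consistent", {
  f <- mkEvents(120, sample(1:3, 120, replace = TRUE), c(50, 170, 330),
                c(1e4, 3e5, 6e5), c(6e5, 1e5, 4e5))
  rows <- buildFeatureTable(f$events, f$coords)
  cm <- clusterPopulations(rows, k = 3, seed = 5)
  X <- cm@features
  expect_true(all(abs(colMeans(X)) < 1e-9))
  expect_true(all(abs(apply(X, 2, sd) - 1) < 1e-9))

  cm2 <- clusterPopulations(rows, k = 3, seed = 5)
  expect_identical(assignments(cm), assignments(cm2))

  ## k = 1: within-SS equals the total variance of the standardised features
  cm1 <- clusterPopulations(rows, k = 1, seed = 5)
  expect_equal(withinSS(cm1)[1], sum(scale(X, scale = FALSE)^2))
  expect_true(all(diff(withinSS(cm)) <= 1e-8))

  ## duplicated rows land in the same cluster
  rows2 <- rbind(rows, rows[7, ])
  cmd <- clusterPopulations(rows2, k = 3, seed = 5)
  expect_equal(assignments(cmd)[7], assignments(cmd)[nrow(rows2)])

  expect_error(clusterPopulations(rows[1:2, ], k = 5), "exceeds")
})

test_that("planted populations are recovered across seeds", {
  aris <- vapply(1:20, function(s) {
    pop <- sample(1:3, 150, replace = TRUE)
    f <- mkEvents(150, pop, c(50, 170, 330),
                  c(1e4, 3e5, 6e5), c(6e5, 1e5, 4e5), seed = 100 + s)
    rows <- buildFeatureTable(f$events, f$coords)
    cm <- clusterPopulations(rows, k = 3, seed = s)
    mclust::adjustedRandIndex(assignments(cm), pop)
  }, numeric(1))
  expect_gte(mean(aris >= 0.9), 0.95)
})

test_that("coordinate scaling lets phenology separate co-located populations", {
  ## same spatial footprint, distinct peak days: clusters must split by
  ## timing, not by distance
  pop <- rep(1:2, each = 60)
  f <- mkEvents(120, pop, c(60, 300), c(3e5, 3e5), c(3e5, 3e5), seed = 77)
  rows <- buildFeatureTable(f$events, f$coords)
  cm <- clusterPopulations(rows, k = 2, seed = 1)
  tab <- table(assignments(cm), pop)
  expect_gte(max(tab[1, 1] + tab[2, 2], tab[1, 2] + tab[2, 1]) / 120, 0.95)
})

test_that("the elbow rule keeps the largest worthwhile k", {
  pop <- rep(1:3, each = 50)
  f <- mkEvents(150, pop, c(50, 170, 330),
                c(1e4, 3e5, 6e5), c(6e5, 1e5, 4e5), seed = 9)
  rows <- buildFeatureTable(f$events, f$coords)
  cm <- clusterPopulations(rows, kMax = 8, seed = 2)
  expect_gte(cm@k, 3)
  expect_length(withinSS(cm), 8)
  summary <- clusterSummary(cm)
  expect_equal(sum(summary$n), 150)
  expect_equal(sum(summary$frequency_pct), 100)
})
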