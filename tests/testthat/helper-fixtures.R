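## Shared fixture builders: everything is generated in code at test time.

## A small world with one pixel per population-free knob we need often.
tinyWorld <- function(rows = 20, cols = 20, px = 32, seed = 3, ...) {
  generateWorld(worldConfig(gridRows = rows, gridCols = cols,
                            patchPixels = px, seed = seed, ...))
}

## One-pixel world with fully controlled phenology (always present).
onePixelWorld <- function(peakDays, durationDays = 80, amplitude = 0.9,
                          seed = 1, ...) {
  generateWorld(worldConfig(
    gridRows = 1, gridCols = 1, nPopulations = length(peakDays),
    peakDays = peakDays, durationDays = durationDays, amplitude = amplitude,
    backgroundFraction = 1,
    covariateLink = c(elevation = 0, slope = 0, treecover = 0),
    twoPeakFraction = if (length(peakDays) > 1) 1 else 0,
    cloudProb = 0, seed = seed, ...))
}

oneYearDates <- function() seq(as.Date("2018-01-01"), by = "day",
                               length.out = 365)

## Separable synthetic patch: green forest vs a centred magenta clump.
separablePatch <- function(bloom, seed, side = 16) {
  set.seed(seed)
  p <- array(0, c(side, side, 4))
  n <- side * side
  p[, , 1] <- 70 + stats::rnorm(n, sd = 6)
  p[, , 2] <- 120 + stats::rnorm(n, sd = 6)
  p[, , 3] <- 60 + stats::rnorm(n, sd = 6)
  p[, , 4] <- 200 + stats::rnorm(n, sd = 6)
  if (bloom) {
    ri <- (side %/% 3):(2 * side %/% 3)
    p[ri, ri, 1] <- p[ri, ri, 1] + 130
    p[ri, ri, 3] <- p[ri, ri, 3] + 130
  }
  pmax(pmin(p, 254), 0)
}

## A MonthlySeries built directly from month-level counts.
msFromCounts <- function(det, obs) {
  structure(list(values = ifelse(obs > 0, det / obs, NA_real_),
                 obsCounts = as.integer(obs),
                 detectionCounts = as.integer(det)),
            class = "MonthlySeries")
}

## Truth-driven monthly binomial series: detection count ~ Bin(nObs, p_m)
## with p_m the monthly mean of the (capped) truth bloom intensity.
simulateMonthlyBinomial <- function(peaks, durations, amplitudes, nObs = 30) {
  days <- seq_len(365)
  m <- vapply(days, function(d) {
    sum(bloomIntensity(d, peaks, durations, amplitudes))
  }, numeric(1))
  m <- pmin(1, m)
  p <- vapply(1:12, function(mm) {
    mean(m[bloomsat:::monthOfDay(days) == mm])
  }, numeric(1))
  det <- stats::rbinom(12, nObs, p)
  msFromCounts(det, rep(nObs, 12))
}

circDist <- function(a, b) pmin(abs(a - b), 365 - abs(a - b))
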