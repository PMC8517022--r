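#' @import methods
NULL

DAYS_PER_YEAR <- 365L

## Circular day-of-year distance, result in [0, 182.5]
circDayDist <- function(a, b, period = DAYS_PER_YEAR) {
  d <- abs(a - b) %% period
  pmin(d, period - d)
}

## Wrap a day value onto 1..365
wrapDay <- function(d, period = DAYS_PER_YEAR) {
  ((round(d) - 1) %% period) + 1
}

## Equal-length month of a day-of-year: month m spans t in [m - 0.5, m + 0.5)
## under the day->month-time mapping t(d) = 12 (d - 0.5) / 365 + 0.5.
monthOfDay <- function(day) {
  m <- floor(12 * (day - 0.5) / DAYS_PER_YEAR) + 1L
  pmin(pmax(as.integer(m), 1L), 12L)
}

## Continuous month-time of a day-of-year (month centres at integer t)
dayToMonthTime <- function(day) {
  12 * (day - 0.5) / DAYS_PER_YEAR + 0.5
}

## Circular month neighbours
prevMonth <- function(m) ifelse(m == 1L, 12L, m - 1L)
nextMonth <- function(m) ifelse(m == 12L, 1L, m + 1L)

## Smooth periodic random field on a grid: white noise convolved with a
## Gaussian kernel along rows then columns (wraps at edges), standardised.
smoothField <- function(rows, cols, range = max(3, round(min(rows, cols) / 5))) {
  z <- matrix(stats::rnorm(rows * cols), rows, cols)
  smooth1 <- function(v) {
    halfw <- min(as.integer(2 * range), (length(v) - 1L) %/% 2L)
    if (halfw < 1) return(v)
    k <- stats::dnorm(seq(-halfw, halfw), sd = range)
    as.numeric(stats::filter(v, k / sum(k), circular = TRUE))
  }
  if (rows > 1) z <- apply(z, 2, smooth1)
  if (cols > 1) z <- t(apply(z, 1, smooth1))
  z <- matrix(as.numeric(z), rows, cols)
  s <- stats::sd(z)
  if (!is.finite(s) || s == 0) return(matrix(0, rows, cols))
  (z - mean(z)) / s
}

## Rescale a field linearly onto [lo, hi]
rescaleField <- function(z, lo, hi) {
  r <- range(z)
  if (diff(r) == 0) return(matrix((lo + hi) / 2, nrow(z), ncol(z)))
  lo + (z - r[1]) / diff(r) * (hi - lo)
}

## Block-aggregate a matrix by an integer factor using the mean (NA-aware).
blockMean <- function(x, factor) {
  stopifnot(factor >= 1, nrow(x) %% factor == 0, ncol(x) %% factor == 0)
  rows <- nrow(x) / factor
  cols <- ncol(x) / factor
  dim(x) <- c(factor, rows, factor, cols)
  out <- apply(x, c(2, 4), function(v) {
    v <- v[!is.na(v)]
    if (length(v) == 0) NA_real_ else mean(v)
  })
  matrix(out, rows, cols)
}

## Fraction of TRUEs per block (logical matrix)
blockFraction <- function(mask, factor) {
  blockMean(matrix(as.numeric(mask), nrow(mask), ncol(mask)), factor)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
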