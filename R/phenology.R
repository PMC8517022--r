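#' Month-of-year normalised detection series for one pixel
#'
#' Pools all years: for each calendar month, the number of detections is
#' divided by the number of cloud-free observations in that month. Months
#' with no cloud-free observation are undefined (\code{NA}).
#'
#' @param states integer state-code vector for one pixel (one per date).
#' @param dates matching \code{Date} vector.
#' @return list of class \code{MonthlySeries}: \code{values} (12 values in
#'   [0,1] or NA), \code{obsCounts}, \code{detectionCounts}.
#' @export
monthlySeries <- function(states, dates) {
  if (length(states) == 0) stop("empty state series")
  stopifnot(length(states) == length(dates))
  m <- as.integer(strftime(as.Date(dates), "%m"))
  obs <- det <- integer(12)
  for (mm in 1:12) {
    sel <- m == mm
    obs[mm] <- sum(states[sel] %in% c(STATE_CLEAR, STATE_DETECTED))
    det[mm] <- sum(states[sel] == STATE_DETECTED)
  }
  if (sum(obs) == 0) {
    vals <- rep(NA_real_, 12)
  } else {
    vals <- ifelse(obs > 0, det / obs, NA_real_)
  }
  structure(list(values = vals, obsCounts = obs, detectionCounts = det),
            class = "MonthlySeries")
}

#' Clean and weight a monthly series for the harmonic fit
#'
#' Applies the data-cleaning rules that precede the seasonal model fit:
#' \enumerate{
#'   \item pixels with fewer than \code{minDetections} detections over the
#'     whole series are excluded (flagged, not an error);
#'   \item isolated peaks supported by only 1 or 2 detections whose two
#'     calendar-neighbour months have no detections are set to 0;
#'   \item values are multiplied by 10;
#'   \item the months immediately before and after each contiguous blooming
#'     run are set to -0.15 x the maximum of the scaled series (blooming
#'     starts and stops fast, so the model is forced below zero there);
#'   \item weights: the (scaled) value itself for positive months, 1 for the
#'     negative shoulder months, 0 for zero months;
#'   \item values and weights are replicated three times (36 points).
#' }
#' Undefined months are treated as zero-valued (and get weight 0).
#'
#' @param series a \code{\link{monthlySeries}}.
#' @param minDetections exclusion floor on total detections.
#' @return list of class \code{CleanedSeries}: \code{values} (36),
#'   \code{weights} (36), \code{scale}, \code{shoulderValue},
#'   \code{zeroWeightMonths} (month-of-year indices), \code{excluded}.
#' @export
cleanSeries <- function(series, minDetections = 4) {
  stopifnot(inherits(series, "MonthlySeries"))
  det <- series$detectionCounts
  if (sum(det) < minDetections) {
    return(structure(list(values = NULL, weights = NULL, scale = 10,
                          shoulderValue = NA_real_,
                          zeroWeightMonths = 1:12, excluded = TRUE),
                     class = "CleanedSeries"))
  }
  v <- series$values
  v[is.na(v)] <- 0

  ## isolated-peak rule on detection counts, both calendar neighbours empty
  orig <- v
  for (m in 1:12) {
    if (det[m] >= 1 && det[m] <= 2 &&
        orig[prevMonth(m)] == 0 && orig[nextMonth(m)] == 0) {
      v[m] <- 0
    }
  }

  v <- v * 10
  shoulder <- -0.15 * max(v)

  pos <- v > 0
  vv <- v
  if (any(pos) && !all(pos)) {
    for (m in which(pos)) {
      pm <- prevMonth(m); nm <- nextMonth(m)
      if (!pos[pm]) vv[pm] <- shoulder
      if (!pos[nm]) vv[nm] <- shoulder
    }
  }
  w <- numeric(12)
  w[vv > 0] <- vv[vv > 0]
  w[vv < 0] <- 1
  structure(list(values = rep(vv, 3), weights = rep(w, 3), scale = 10,
                 shoulderValue = shoulder,
                 zeroWeightMonths = which(w == 0), excluded = FALSE),
            class = "CleanedSeries")
}

## Harmonic design matrix at month-times t for the 4-, 6- and 12-month periods
harmonicBasis <- function(t) {
  cbind(1,
        sin(2 * pi * t / 4),  cos(2 * pi * t / 4),
        sin(2 * pi * t / 6),  cos(2 * pi * t / 6),
        sin(2 * pi * t / 12), cos(2 * pi * t / 12))
}

## Evaluate the eight-parameter model at month-times t
evalBloomModel <- function(fit, t) {
  fit@bloom0 + fit@pow0 *
    (fit@p4 * sin(2 * pi * t / 4 + fit@rho4) +
       fit@p6 * sin(2 * pi * t / 6 + fit@rho6) +
       fit@p12 * sin(2 * pi * t / 12 + fit@rho12))
}

#' Fit the constrained three-harmonic flowering model
#'
#' Fits \deqn{bloom(t) = bloom0 + pow0 (p4 sin(2 pi t/4 + rho4) +
#' p6 sin(2 pi t/6 + rho6) + p12 sin(2 pi t/12 + rho12))} with
#' \eqn{p4 + p6 + p12 = 1} to the 36 cleaned points by weighted least
#' squares. Because each component
#' \eqn{A sin(\omega t + \rho) = a sin(\omega t) + b cos(\omega t)}, the
#' model is linear in the sine/cosine basis: the fit is the exact weighted
#' linear least-squares solution, with \eqn{A_k = \sqrt{a_k^2+b_k^2}},
#' \eqn{\rho_k = atan2(b_k, a_k)}, \eqn{pow0 = \sum_k A_k} and
#' \eqn{p_k = A_k / pow0}. This makes the fit deterministic and global --
#' no iterative optimiser or initialisation.
#'
#' @param cleaned a non-excluded \code{\link{cleanSeries}} result, or any
#'   list with \code{values} and \code{weights} of equal length.
#' @return a \code{\linkS4class{BloomFit}}. The weighted R-squared is
#'   computed over the positively weighted points; a degenerate zero-power
#'   fit (constant series) reports R-squared 1 by convention.
#' @export
fitBloomModel <- function(cleaned) {
  y <- cleaned$values
  w <- cleaned$weights
  if (is.null(y)) stop("cannot fit an excluded series")
  stopifnot(length(y) == length(w))
  if (all(w <= 0)) stop("all weights are zero")
  t <- seq_along(y)
  X <- harmonicBasis(t)
  ## minimum-norm weighted least squares via the SVD pseudoinverse: equal to
  ## the exact WLS solution when the weighted design has full rank, and the
  ## smallest-coefficient (least-ringing) solution when few months carry
  ## positive weight and the harmonics are not all identifiable
  sw <- sqrt(w)
  sv <- svd(X * sw)
  keep <- sv$d > max(sv$d) * 1e-10
  cf <- sv$v[, keep, drop = FALSE] %*%
    ((crossprod(sv$u[, keep, drop = FALSE], y * sw)) / sv$d[keep])
  cf <- as.numeric(cf)
  amp <- function(a, b) sqrt(a^2 + b^2)
  A <- c(amp(cf[2], cf[3]), amp(cf[4], cf[5]), amp(cf[6], cf[7]))
  pow0 <- sum(A)
  if (pow0 > 0) {
    p <- A / pow0
    rho <- c(atan2(cf[3], cf[2]), atan2(cf[5], cf[4]), atan2(cf[7], cf[6]))
    rho[A == 0] <- 0
  } else {
    p <- c(0, 0, 1)       # simplex kept; phases meaningless at zero power
    rho <- c(0, 0, 0)
  }
  fitted <- as.numeric(X %*% cf)
  sel <- w > 0
  ybar <- sum(w[sel] * y[sel]) / sum(w[sel])
  ssTot <- sum(w[sel] * (y[sel] - ybar)^2)
  ssRes <- sum(w[sel] * (y[sel] - fitted[sel])^2)
  r2 <- if (ssTot <= .Machine$double.eps * max(1, sum(w))) 1 else 1 - ssRes / ssTot
  new("BloomFit", bloom0 = cf[1], pow0 = pow0,
      p4 = p[1], p6 = p[2], p12 = p[3],
      rho4 = rho[1], rho6 = rho[2], rho12 = rho[3],
      weightedR2 = min(1, r2), fitted = fitted,
      nRep = as.integer(length(y) / 12))
}

#' Reconstruct the daily flowering signal
#'
#' Evaluates the fitted model over one circular year at
#' \eqn{t(d) = 12 (d - 0.5) / 365 + 0.5} for d = 1..365 (month centres map
#' to integer t), clamps negative predictions to 0, and zeroes every day of
#' the zero-weight months.
#'
#' @param fit a \code{\linkS4class{BloomFit}}.
#' @param zeroWeightMonths month-of-year indices whose days are forced to 0
#'   (from \code{\link{cleanSeries}}).
#' @return numeric vector of 365 non-negative daily values.
#' @export
reconstructDaily <- function(fit, zeroWeightMonths = integer(0)) {
  d <- seq_len(DAYS_PER_YEAR)
  y <- evalBloomModel(fit, dayToMonthTime(d))
  y[y < 0] <- 0
  if (length(zeroWeightMonths))
    y[monthOfDay(d) %in% zeroWeightMonths] <- 0
  y
}

## Circular neighbours helper on a 365-vector
circShift <- function(x, k) {
  n <- length(x)
  x[((seq_len(n) - 1 - k) %% n) + 1]
}

#' Extract flowering events from a daily series
#'
#' Peaks are circular local maxima with positive value (plateau maxima
#' report their first day). Each event spans from the nearest preceding to
#' the nearest following pit-or-zero day, walking circularly; a pit is a
#' circular local minimum. Events are sorted by peak day.
#'
#' @param daily 365 non-negative daily values.
#' @return data.frame with columns start_day, peak_day, end_day, peak_value,
#'   duration_days (circular span start to end); zero rows when nothing
#'   blooms.
#' @export
extractBloomEvents <- function(daily) {
  n <- length(daily)
  stopifnot(n == DAYS_PER_YEAR)
  empty <- data.frame(start_day = integer(), peak_day = integer(),
                      end_day = integer(), peak_value = numeric(),
                      duration_days = numeric())
  if (all(daily <= 0)) return(empty)
  prv <- circShift(daily, 1)   # value of the previous day
  nxt <- circShift(daily, -1)  # value of the next day

  ## plateau-aware circular local maxima: first day of each maximal run
  runStart <- daily != prv
  if (!any(runStart)) return(empty)  # constant positive circle: no peaks
  peaks <- integer(0)
  starts <- which(runStart)
  for (s in starts) {
    ## run of equal values starting at s
    e <- s
    while (daily[e %% n + 1] == daily[s]) {
      e <- e %% n + 1
      if (e == s) break
    }
    before <- daily[((s - 2) %% n) + 1]
    after <- daily[e %% n + 1]
    if (daily[s] > 0 && daily[s] > before && daily[s] > after)
      peaks <- c(peaks, s)
  }
  if (length(peaks) == 0) return(empty)

  isBoundary <- daily == 0 | (daily <= prv & daily <= nxt & (daily < prv | daily < nxt))
  boundary <- which(isBoundary)
  events <- lapply(peaks, function(pk) {
    back <- ((pk - 1 - seq_len(n - 1)) %% n) + 1
    fwd <- ((pk - 1 + seq_len(n - 1)) %% n) + 1
    s <- back[match(TRUE, back %in% boundary)]
    e <- fwd[match(TRUE, fwd %in% boundary)]
    if (is.na(s)) s <- pk
    if (is.na(e)) e <- pk
    dur <- (e - s) %% n
    if (dur == 0) dur <- n   # single pit: the episode wraps the whole year
    data.frame(start_day = s, peak_day = pk, end_day = e,
               peak_value = daily[pk], duration_days = dur)
  })
  out <- do.call(rbind, events)
  out[order(out$peak_day), , drop = FALSE]
}

#' Fit one pixel end to end
#'
#' Convenience wrapper: monthly normalisation, cleaning, harmonic fit,
#' daily reconstruction and event extraction for a single pixel's state
#' series. Peaks and pits are identified on the continuous (negative-clamped)
#' model curve before the month-zeroing step; peaks whose day falls inside a
#' zero-weight month are discarded, since months without any detection cannot
#' host a blooming episode. Zeroing a rising model excursion would otherwise
#' manufacture a spurious local maximum at the truncation edge.
#'
#' @param states,dates the pixel's observation states and dates.
#' @param minDetections cleaning exclusion floor.
#' @return list with \code{monthly}, \code{cleaned}, \code{fit},
#'   \code{daily} (the month-zeroed reported series), \code{events};
#'   or \code{NULL} when the pixel is excluded.
#' @export
fitPixelPhenology <- function(states, dates, minDetections = 4) {
  ms <- monthlySeries(states, dates)
  cs <- cleanSeries(ms, minDetections = minDetections)
  if (cs$excluded) return(NULL)
  if (all(cs$weights <= 0)) return(NULL)
  fit <- fitBloomModel(cs)
  dailyFull <- reconstructDaily(fit)
  events <- extractBloomEvents(dailyFull)
  if (nrow(events) > 0)
    events <- events[!(monthOfDay(events$peak_day) %in% cs$zeroWeightMonths), ,
                     drop = FALSE]
  daily <- reconstructDaily(fit, cs$zeroWeightMonths)
  list(monthly = ms, cleaned = cs, fit = fit, daily = daily, events = events)
}
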