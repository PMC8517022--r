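#' Build the event feature table for population clustering
#'
#' One row per flowering event (a two-peak pixel contributes two rows):
#' start/peak/end day-of-year, the reconstructed bloom values at those days,
#' and the metric xy coordinates divided by 100,000 and rounded to the
#' nearest unit, so that raw distance does not dominate the variance.
#'
#' @param events data.frame of events with a \code{pixel_id} column and the
#'   \code{\link{extractBloomEvents}} columns, plus per-event bloom values
#'   \code{start_value}, \code{peak_value}, \code{end_value} (missing value
#'   columns are tolerated).
#' @param coordinates data.frame with \code{pixel_id}, \code{x}, \code{y}
#'   in metres.
#' @return data.frame of class rows ready for \code{\link{clusterPopulations}}.
#' @export
buildFeatureTable <- function(events, coordinates) {
  if (nrow(events) == 0) {
    return(data.frame(pixel_id = integer(), start_day = numeric(),
                      peak_day = numeric(), end_day = numeric(),
                      start_value = numeric(), peak_value = numeric(),
                      end_value = numeric(), x_scaled = numeric(),
                      y_scaled = numeric()))
  }
  m <- match(events$pixel_id, coordinates$pixel_id)
  if (anyNA(m)) stop("event without coordinates")
  for (col in c("start_value", "end_value"))
    if (is.null(events[[col]])) events[[col]] <- 0
  data.frame(
    pixel_id = events$pixel_id,
    start_day = events$start_day, peak_day = events$peak_day,
    end_day = events$end_day,
    start_value = events$start_value, peak_value = events$peak_value,
    end_value = events$end_value,
    x_scaled = round(coordinates$x[m] / 1e5),
    y_scaled = round(coordinates$y[m] / 1e5))
}

#' K-means clustering of flowering events into populations
#'
#' Standardises every feature column (zero mean, unit SD; constant columns
#' are dropped), then runs seeded multi-restart K-means. When \code{k} is
#' not given, the total within-cluster sum of squares is computed for
#' k = 1..\code{kMax} and k is chosen as the largest k whose relative
#' within-SS decrease still exceeds \code{elbowThreshold} -- the elbow read
#' so as to keep the maximum number of clusters.
#'
#' @param rows feature table from \code{\link{buildFeatureTable}}.
#' @param k number of clusters; \code{NULL} to choose from the elbow curve.
#' @param kMax largest k scanned for the elbow curve.
#' @param seed RNG seed.
#' @param elbowThreshold minimum relative within-SS drop (default 2\%).
#' @param nstart,iterMax K-means restarts and iteration cap.
#' @return a \code{\linkS4class{ClusterModel}}; its summary table reports,
#'   per cluster, the size, the frequency in percent, and the mean and modal
#'   member peak day.
#' @export
clusterPopulations <- function(rows, k = NULL, kMax = 15, seed = 1L,
                               elbowThreshold = 0.02, nstart = 10,
                               iterMax = 300) {
  featCols <- setdiff(names(rows), "pixel_id")
  X <- as.matrix(rows[, featCols, drop = FALSE])
  if (!is.null(k) && k > nrow(X)) stop("k exceeds the number of rows")
  sds <- apply(X, 2, stats::sd)
  X <- scale(X[, sds > 0, drop = FALSE])
  kMax <- min(kMax, nrow(unique(X)))

  withinSS <- numeric(kMax)
  set.seed(seed)
  for (kk in seq_len(kMax)) {
    km <- stats::kmeans(X, centers = kk, nstart = nstart, iter.max = iterMax)
    withinSS[kk] <- km$tot.withinss
  }
  withinSS <- cummin(withinSS)  # guard tiny restart noise; curve is non-increasing
  if (is.null(k)) {
    if (kMax == 1) {
      k <- 1L
    } else {
      rel <- -diff(withinSS) / withinSS[-kMax]
      good <- which(rel > elbowThreshold)
      k <- if (length(good)) max(good) + 1L else 1L
    }
  }
  set.seed(seed)
  km <- stats::kmeans(X, centers = k, nstart = nstart, iter.max = iterMax)

  cl <- km$cluster
  meanDay <- tapply(rows$peak_day, cl, mean)
  modalDay <- tapply(rows$peak_day, cl, function(d) {
    ud <- sort(unique(d))
    ud[which.max(tabulate(match(d, ud)))]
  })
  summaryTab <- data.frame(
    cluster = as.integer(names(table(cl))),
    n = as.integer(table(cl)),
    frequency_pct = 100 * as.integer(table(cl)) / length(cl),
    mean_peak_day = as.numeric(meanDay),
    modal_peak_day = as.numeric(modalDay))
  summaryTab <- summaryTab[order(summaryTab$mean_peak_day), ]

  new("ClusterModel", k = as.integer(k), centers = km$centers,
      assignments = as.integer(cl), withinSSCurve = withinSS,
      features = X, summary = summaryTab, seed = as.integer(seed))
}
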