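#' Spatialise patch predictions onto the coarse presence grid
#'
#' Each core cell of the tiling grid receives its patch's 0/1 prediction:
#' a 10240-pixel scene yields an 80 x 80 raster at 1280 m resolution.
#' Predictions are taken in the row-major patch order that
#' \code{\link{tileScene}} emits.
#'
#' @param predictions integer 0/1 vector, one per grid cell.
#' @param gridDims c(rows, cols) of the tiling grid (the \code{gridDims}
#'   attribute of the \code{tileScene} output).
#' @return integer matrix rows x cols.
#' @export
spatializePredictions <- function(predictions, gridDims) {
  nR <- gridDims[1]; nC <- gridDims[2]
  if (length(predictions) != nR * nC)
    stop(sprintf("expected %d predictions for a %d x %d grid, got %d",
                 nR * nC, nR, nC, length(predictions)))
  matrix(as.integer(predictions), nR, nC, byrow = TRUE)
}

#' Cell-level cloud fraction of a pixel cloud mask
#'
#' @param cloudMask logical pixel mask.
#' @param core pixels per cell side.
#' @return numeric matrix of per-cell cloud fractions.
#' @export
cellCloudFraction <- function(cloudMask, core) {
  blockFraction(cloudMask, core)
}

#' Accumulate per-scene detections into daily observation states
#'
#' For each grid pixel and calendar day: \emph{detected} when a scene that
#' day predicted presence and the cell is not cloud-covered; \emph{cloud}
#' when the cell's cloud fraction exceeds \code{cloudCellThreshold} (cloud
#' overrides detection, so cloud artefacts are not counted); \emph{clear}
#' otherwise; \emph{missing} when no scene covers the day. Same-day
#' duplicate scenes (overlapping orbits) merge by OR on detection and AND on
#' cloud: a detection in either replicate is a real observation.
#'
#' @param presenceList list of 0/1 matrices, one per scene.
#' @param cloudFracList list of per-cell cloud-fraction matrices.
#' @param sceneDates \code{Date} vector, one per scene.
#' @param studyDates all days of the series; defaults to the full span of
#'   \code{sceneDates}.
#' @param cloudCellThreshold fraction above which a 1280 m cell is cloud.
#' @return an \code{\linkS4class{ObservationSeries}}.
#' @export
accumulateDailyStates <- function(presenceList, cloudFracList, sceneDates,
                                  studyDates = NULL,
                                  cloudCellThreshold = 0.5) {
  stopifnot(length(presenceList) == length(sceneDates),
            length(cloudFracList) == length(sceneDates))
  dims <- dim(presenceList[[1]])
  for (i in seq_along(presenceList))
    if (!identical(dim(presenceList[[i]]), dims) ||
        !identical(dim(cloudFracList[[i]]), dims))
      stop("all rasters must share the same grid")
  sceneDates <- as.Date(sceneDates)
  if (is.null(studyDates))
    studyDates <- seq(min(sceneDates), max(sceneDates), by = "day")
  states <- array(STATE_MISSING, dim = c(dims[1], dims[2], length(studyDates)))
  for (d in seq_along(studyDates)) {
    hit <- which(sceneDates == studyDates[d])
    if (length(hit) == 0) next
    det <- matrix(FALSE, dims[1], dims[2])
    cld <- matrix(TRUE, dims[1], dims[2])
    for (i in hit) {
      ci <- cloudFracList[[i]] > cloudCellThreshold
      det <- det | (presenceList[[i]] > 0 & !ci)
      cld <- cld & ci
    }
    st <- matrix(STATE_CLEAR, dims[1], dims[2])
    st[det] <- STATE_DETECTED
    st[cld] <- STATE_CLOUD
    states[, , d] <- st
  }
  new("ObservationSeries", states = states, dates = studyDates)
}

#' Detection-frequency map
#'
#' Per-pixel detection frequency in percent of cloud-free observations,
#' with pixels below the detection floor forced to zero, plus descriptive
#' statistics: the median frequency over nonzero pixels with its percentile
#' interval, and the fraction of pixels with at least one detection in every
#' 12-month window of the series.
#'
#' @param obs an \code{\linkS4class{ObservationSeries}}.
#' @param minDetections pixels with fewer detections are set to 0.
#' @param percentiles bounds of the descriptive interval (the conventional
#'   printed interval is percentile 2.75 to 97.5).
#' @return a \code{\linkS4class{DetectionSummary}}.
#' @export
frequencyMap <- function(obs, minDetections = 4,
                         percentiles = c(0.0275, 0.975)) {
  st <- obs@states
  if (dim(st)[3] < 1) stop("need at least one date")
  count <- function(code) apply(st == code, c(1, 2), sum)
  nDet <- count(STATE_DETECTED)
  nClear <- count(STATE_CLEAR)
  nCloud <- count(STATE_CLOUD)
  nMissing <- count(STATE_MISSING)
  cloudFree <- nDet + nClear
  freq <- ifelse(cloudFree > 0, 100 * nDet / cloudFree, NA_real_)
  freq[!is.na(freq) & nDet < minDetections] <- 0

  ## at least one detection in every 12-month window of the span
  dates <- obs@dates
  nYears <- max(1L, ceiling(as.integer(max(dates) - min(dates) + 1) / 365))
  everyYear <- matrix(TRUE, dim(st)[1], dim(st)[2])
  for (yr in seq_len(nYears)) {
    sel <- dates >= min(dates) + (yr - 1) * 365 & dates < min(dates) + yr * 365
    if (!any(sel)) next
    detYr <- apply(st[, , sel, drop = FALSE] == STATE_DETECTED, c(1, 2), any)
    everyYear <- everyYear & detYr
  }
  nz <- freq[!is.na(freq) & freq > 0]
  stats <- list(
    fractionDetectedEveryYear = mean(everyYear),
    medianFrequency = if (length(nz)) stats::median(nz) else NA_real_,
    frequencyInterval = if (length(nz))
      stats::quantile(nz, percentiles, names = FALSE) else c(NA_real_, NA_real_),
    percentiles = percentiles)
  new("DetectionSummary", nDetected = nDet, nClear = nClear,
      nCloud = nCloud, nMissing = nMissing, frequencyPct = freq,
      minDetections = minDetections, stats = stats)
}
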