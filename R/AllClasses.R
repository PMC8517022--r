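## Observation-state codes shared across the package. Exactly one state per
## (pixel, date): missing (no scene), clear (observed, no bloom), detected
## (observed with bloom), cloud (observed but cloud-covered).
STATE_MISSING  <- 0L
STATE_CLEAR    <- 1L
STATE_DETECTED <- 2L
STATE_CLOUD    <- 3L

#' SceneStack: one dated four-band reflectance scene
#'
#' Holds the red, green, blue and near-infrared bands of a single acquisition
#' together with its cloud and nodata masks. Values are integer top-of-
#' atmosphere reflectances: 0--10000 for 12-bit scenes, 0--254 after 8-bit
#' conversion (see \code{\link{convertTo8Bit}}).
#'
#' @slot red,green,blue,nir integer band matrices (rows x cols), identical shape.
#' @slot date acquisition date (\code{Date}).
#' @slot cloudMask logical matrix flagging cloud pixels.
#' @slot nodataMask logical matrix flagging pixels with no data.
#' @slot bitDepth 12 (raw) or 8 (converted).
#' @exportClass SceneStack
setClass("SceneStack", representation(
  red = "matrix", green = "matrix", blue = "matrix", nir = "matrix",
  date = "Date", cloudMask = "matrix", nodataMask = "matrix",
  bitDepth = "numeric"
))

setValidity("SceneStack", function(object) {
  dims <- lapply(list(object@red, object@green, object@blue, object@nir,
                      object@cloudMask, object@nodataMask), dim)
  if (!all(vapply(dims, identical, logical(1), dims[[1]])))
    return("all bands and masks must share the same dimensions")
  if (!object@bitDepth %in% c(8, 12))
    return("bitDepth must be 8 or 12")
  top <- if (object@bitDepth == 12) 10000 else 254
  vals <- c(object@red, object@green, object@blue, object@nir)
  if (any(vals < 0 | vals > top, na.rm = TRUE))
    return(sprintf("band values must lie in [0, %d]", top))
  TRUE
})

#' SyntheticWorld: a seeded ground-truth world for the pipeline
#'
#' A presence grid of coarse (one-detection-cell) pixels, a phenology truth
#' table (one or two rows per presence pixel: population, amplitude, peak day,
#' duration, start/end day), six environmental covariate grids, the per-
#' population parameters, and the generating configuration.
#'
#' @slot presence logical matrix (rows x cols) of blooming-stand presence.
#' @slot phenologyTruth data.frame with columns row, col, population,
#'   amplitude, peak_day, duration_days, start_day, end_day.
#' @slot covariates named list of six numeric matrices: elevation (m),
#'   slope (deg), treecover (pct), precipitation (mm/yr), tmin (C), tmax (C).
#' @slot populations data.frame of per-population centres and phenology.
#' @slot config the \code{\link{worldConfig}} list used to generate the world.
#' @exportClass SyntheticWorld
setClass("SyntheticWorld", representation(
  presence = "matrix", phenologyTruth = "data.frame",
  covariates = "list", populations = "data.frame", config = "list"
))

setValidity("SyntheticWorld", function(object) {
  if (!is.logical(object@presence)) return("presence must be a logical matrix")
  for (cv in object@covariates)
    if (!identical(dim(cv), dim(object@presence)))
      return("covariate grids must share the presence grid shape")
  tt <- object@phenologyTruth
  if (nrow(tt) > 0) {
    if (any(!tt$row %in% seq_len(nrow(object@presence))) ||
        any(!tt$col %in% seq_len(ncol(object@presence))))
      return("phenology truth indices outside the grid")
    if (any(!object@presence[cbind(tt$row, tt$col)]))
      return("phenology truth rows must correspond to presence pixels")
    if (any(tt$peak_day < 1 | tt$peak_day > 365))
      return("peak_day must lie in [1, 365]")
  }
  TRUE
})

#' ObservationSeries: daily per-pixel observation states
#'
#' A rows x cols x nDates integer array of observation states (codes:
#' 0 missing, 1 clear, 2 detected, 3 cloud) with the corresponding dates.
#'
#' @slot states integer array, dim = c(rows, cols, nDates).
#' @slot dates Date vector of length nDates.
#' @exportClass ObservationSeries
setClass("ObservationSeries", representation(
  states = "array", dates = "Date"
))

setValidity("ObservationSeries", function(object) {
  d <- dim(object@states)
  if (length(d) != 3) return("states must be a 3-d array")
  if (d[3] != length(object@dates))
    return("third dimension must match the number of dates")
  if (!all(object@states %in% c(STATE_MISSING, STATE_CLEAR,
                                STATE_DETECTED, STATE_CLOUD)))
    return("invalid state codes")
  TRUE
})

#' DetectionSummary: per-pixel detection bookkeeping and frequency
#'
#' Counts of detected / clear / cloud / missing dates per grid pixel, and the
#' detection frequency in percent of cloud-free observations
#' (100 * detected / (detected + clear)). Pixels with fewer than
#' \code{minDetections} detections are forced to zero frequency; pixels with
#' no cloud-free observation are \code{NA}.
#'
#' @slot nDetected,nClear,nCloud,nMissing integer count matrices.
#' @slot frequencyPct numeric matrix in [0, 100] or NA.
#' @slot minDetections the floor applied to the frequency map.
#' @slot stats named list of descriptive statistics (median over nonzero
#'   pixels, percentile interval, fraction of pixels with at least one
#'   detection per 12-month window).
#' @exportClass DetectionSummary
setClass("DetectionSummary", representation(
  nDetected = "matrix", nClear = "matrix", nCloud = "matrix",
  nMissing = "matrix", frequencyPct = "matrix",
  minDetections = "numeric", stats = "list"
))

#' BloomFit: the eight-parameter three-harmonic flowering model
#'
#' Parameters of the seasonal model
#' \deqn{bloom(t) = bloom0 + pow0 (p4 sin(2 pi t / 4 + rho4)
#'   + p6 sin(2 pi t / 6 + rho6) + p12 sin(2 pi t / 12 + rho12))}
#' with \eqn{p4 + p6 + p12 = 1}, fitted to a cleaned 36-month series by
#' weighted least squares, plus the weighted R-squared over positively
#' weighted points.
#'
#' @slot bloom0 mean level.
#' @slot pow0 signal power (sum of component amplitudes), >= 0.
#' @slot p4,p6,p12 relative proportions of the 4-, 6- and 12-month periods.
#' @slot rho4,rho6,rho12 phase delays in radians.
#' @slot weightedR2 weighted coefficient of determination, <= 1.
#' @slot fitted fitted values at the 36 month points.
#' @slot nRep series replication count (3).
#' @exportClass BloomFit
setClass("BloomFit", representation(
  bloom0 = "numeric", pow0 = "numeric",
  p4 = "numeric", p6 = "numeric", p12 = "numeric",
  rho4 = "numeric", rho6 = "numeric", rho12 = "numeric",
  weightedR2 = "numeric", fitted = "numeric", nRep = "integer"
))

setValidity("BloomFit", function(object) {
  if (object@pow0 < -1e-9) return("pow0 must be non-negative")
  p <- c(object@p4, object@p6, object@p12)
  if (any(p < -1e-9)) return("period proportions must be non-negative")
  if (abs(sum(p) - 1) > 1e-9) return("p4 + p6 + p12 must equal 1")
  if (object@weightedR2 > 1 + 1e-12) return("weighted R2 cannot exceed 1")
  TRUE
})

#' ClusterModel: K-means phenological populations
#'
#' @slot k number of clusters used.
#' @slot centers centroid matrix in standardised feature space.
#' @slot assignments integer cluster label per feature row.
#' @slot withinSSCurve total within-cluster sum of squares for k = 1..kMax.
#' @slot features the standardised feature matrix sent to K-means.
#' @slot summary per-cluster summary (n, frequency pct, mean/modal peak day).
#' @slot seed RNG seed used.
#' @exportClass ClusterModel
setClass("ClusterModel", representation(
  k = "integer", centers = "matrix", assignments = "integer",
  withinSSCurve = "numeric", features = "matrix",
  summary = "data.frame", seed = "integer"
))

setValidity("ClusterModel", function(object) {
  if (length(object@assignments) != nrow(object@features))
    return("one assignment per feature row required")
  if (is.unsorted(-object@withinSSCurve, strictly = FALSE) &&
      any(diff(object@withinSSCurve) > 1e-6 * object@withinSSCurve[1]))
    return("within-SS curve must be non-increasing in k")
  TRUE
})

#' AssociationResult: decile-class bootstrap association test
#'
#' Observed presence counts per covariate quantile class against the
#' bootstrap null of uniformly random locations over the domain.
#'
#' @slot table data.frame with one row per class: class, lower, upper,
#'   observed, null_mean, ci_low, ci_high, significant, proportion_pct.
#' @slot B number of bootstrap replicates.
#' @slot nPresence number of presence pixels tested.
#' @slot ciProbs the two percentile bounds of the null interval.
#' @slot seed RNG seed used.
#' @exportClass AssociationResult
setClass("AssociationResult", representation(
  table = "data.frame", B = "integer", nPresence = "integer",
  ciProbs = "numeric", seed = "integer"
))

setValidity("AssociationResult", function(object) {
  tb <- object@table
  need <- c("class", "observed", "null_mean", "ci_low", "ci_high",
            "significant", "proportion_pct")
  if (!all(need %in% names(tb))) return("missing columns in result table")
  sig <- tb$observed < tb$ci_low | tb$observed > tb$ci_high
  if (!identical(as.logical(tb$significant), as.logical(sig)))
    return("significance flags inconsistent with the interval")
  TRUE
})
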