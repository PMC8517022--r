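#' Construct a SceneStack
#'
#' @param red,green,blue,nir integer band matrices of identical shape.
#' @param date acquisition date (coerced with \code{as.Date}).
#' @param cloudMask,nodataMask logical matrices; default all-\code{FALSE}.
#' @param bitDepth 12 for raw reflectance (0--10000), 8 after conversion.
#' @return a \code{\linkS4class{SceneStack}}.
#' @export
SceneStack <- function(red, green, blue, nir, date,
                       cloudMask = NULL, nodataMask = NULL, bitDepth = 12) {
  dims <- dim(red)
  if (is.null(cloudMask)) cloudMask <- matrix(FALSE, dims[1], dims[2])
  if (is.null(nodataMask)) nodataMask <- matrix(FALSE, dims[1], dims[2])
  new("SceneStack", red = red, green = green, blue = blue, nir = nir,
      date = as.Date(date), cloudMask = cloudMask, nodataMask = nodataMask,
      bitDepth = bitDepth)
}

#' @describeIn SceneStack-class cloud fraction over valid (non-nodata) pixels.
#' @export
setMethod("cloudFraction", "SceneStack", function(object) {
  valid <- !object@nodataMask
  if (!any(valid)) return(NA_real_)
  mean(object@cloudMask[valid])
})

#' @describeIn SceneStack-class list of the four band matrices.
#' @param x a \code{SceneStack}
#' @export
sceneBands <- function(x) {
  list(red = x@red, green = x@green, blue = x@blue, nir = x@nir)
}

#' @export
sceneDate <- function(x) x@date

#' @export
sceneCloudMask <- function(x) x@cloudMask

#' @export
sceneNodataMask <- function(x) x@nodataMask

setMethod("show", "SceneStack", function(object) {
  cat(sprintf("SceneStack %s: %d x %d px, %d-bit, cloud %.1f%%\n",
              format(object@date), nrow(object@red), ncol(object@red),
              as.integer(object@bitDepth), 100 * cloudFraction(object)))
})

#' @describeIn SyntheticWorld-class logical presence grid.
#' @export
setMethod("presence", "SyntheticWorld", function(object) object@presence)

#' @describeIn SyntheticWorld-class named list of covariate grids.
#' @export
setMethod("covariates", "SyntheticWorld", function(object) object@covariates)

#' @describeIn SyntheticWorld-class ground-truth phenology table.
#' @export
setMethod("phenologyTruth", "SyntheticWorld", function(object) object@phenologyTruth)

#' @export
worldPopulations <- function(x) x@populations

#' @export
worldConfigOf <- function(x) x@config

setMethod("show", "SyntheticWorld", function(object) {
  cat(sprintf("SyntheticWorld: %d x %d cells, %d presence pixels, %d populations\n",
              nrow(object@presence), ncol(object@presence),
              sum(object@presence), nrow(object@populations)))
})

#' @describeIn ObservationSeries-class the state array.
#' @export
setMethod("obsStates", "ObservationSeries", function(object) object@states)

#' @describeIn ObservationSeries-class the date vector.
#' @export
setMethod("obsDates", "ObservationSeries", function(object) object@dates)

setMethod("show", "ObservationSeries", function(object) {
  d <- dim(object@states)
  cat(sprintf("ObservationSeries: %d x %d pixels, %d dates (%s .. %s)\n",
              d[1], d[2], d[3], format(min(object@dates)),
              format(max(object@dates))))
})

#' @describeIn DetectionSummary-class detection-frequency matrix (percent).
#' @export
setMethod("frequencyPct", "DetectionSummary", function(object) object@frequencyPct)

#' @describeIn DetectionSummary-class list of the four count matrices.
#' @export
setMethod("detectionCounts", "DetectionSummary", function(object) {
  list(detected = object@nDetected, clear = object@nClear,
       cloud = object@nCloud, missing = object@nMissing)
})

#' @export
summaryStats <- function(x) x@stats

setMethod("show", "DetectionSummary", function(object) {
  nz <- object@frequencyPct[!is.na(object@frequencyPct) & object@frequencyPct > 0]
  cat(sprintf("DetectionSummary: %d x %d pixels, %d with nonzero frequency (median %.1f%%)\n",
              nrow(object@frequencyPct), ncol(object@frequencyPct),
              length(nz), if (length(nz)) stats::median(nz) else NA))
})

#' @describeIn BloomFit-class named vector of the eight model parameters.
#' @export
setMethod("bloomParams", "BloomFit", function(object) {
  c(bloom0 = object@bloom0, pow0 = object@pow0,
    p4 = object@p4, p6 = object@p6, p12 = object@p12,
    rho4 = object@rho4, rho6 = object@rho6, rho12 = object@rho12)
})

#' @export
weightedR2 <- function(x) x@weightedR2

setMethod("show", "BloomFit", function(object) {
  cat(sprintf(paste0("BloomFit: bloom0=%.3f pow0=%.3f p=(%.2f, %.2f, %.2f) ",
                     "rho=(%.2f, %.2f, %.2f) wR2=%.4f\n"),
              object@bloom0, object@pow0, object@p4, object@p6, object@p12,
              object@rho4, object@rho6, object@rho12, object@weightedR2))
})

#' @describeIn ClusterModel-class integer cluster label per event row.
#' @export
setMethod("assignments", "ClusterModel", function(object) object@assignments)

#' @describeIn ClusterModel-class total within-cluster SS for k = 1..kMax.
#' @export
setMethod("withinSS", "ClusterModel", function(object) object@withinSSCurve)

#' @export
clusterSummary <- function(x) x@summary

setMethod("show", "ClusterModel", function(object) {
  cat(sprintf("ClusterModel: k=%d over %d events\n",
              object@k, length(object@assignments)))
  print(object@summary, row.names = FALSE)
})

#' @describeIn AssociationResult-class per-class result table.
#' @export
setMethod("associationTable", "AssociationResult", function(object) object@table)

setMethod("show", "AssociationResult", function(object) {
  cat(sprintf("AssociationResult: %d classes, N=%d, B=%d\n",
              nrow(object@table), object@nPresence, object@B))
  print(object@table, row.names = FALSE, digits = 4)
})
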