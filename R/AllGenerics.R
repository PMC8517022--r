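#' @rdname SceneStack-class
#' @param object a \code{SceneStack}
#' @export
setGeneric("cloudFraction", function(object) standardGeneric("cloudFraction"))

#' @rdname SyntheticWorld-class
#' @param object an object with a presence grid
#' @export
setGeneric("presence", function(object) standardGeneric("presence"))

#' @rdname SyntheticWorld-class
#' @export
setGeneric("covariates", function(object) standardGeneric("covariates"))

#' @rdname SyntheticWorld-class
#' @export
setGeneric("phenologyTruth", function(object) standardGeneric("phenologyTruth"))

#' @rdname ObservationSeries-class
#' @param object an \code{ObservationSeries}
#' @export
setGeneric("obsStates", function(object) standardGeneric("obsStates"))

#' @rdname ObservationSeries-class
#' @export
setGeneric("obsDates", function(object) standardGeneric("obsDates"))

#' @rdname DetectionSummary-class
#' @param object a \code{DetectionSummary}
#' @export
setGeneric("frequencyPct", function(object) standardGeneric("frequencyPct"))

#' @rdname DetectionSummary-class
#' @export
setGeneric("detectionCounts", function(object) standardGeneric("detectionCounts"))

#' @rdname BloomFit-class
#' @param object a \code{BloomFit}
#' @export
setGeneric("bloomParams", function(object) standardGeneric("bloomParams"))

#' @rdname ClusterModel-class
#' @param object a \code{ClusterModel}
#' @export
setGeneric("assignments", function(object) standardGeneric("assignments"))

#' @rdname ClusterModel-class
#' @export
setGeneric("withinSS", function(object) standardGeneric("withinSS"))

#' @rdname AssociationResult-class
#' @param object an \code{AssociationResult}
#' @export
setGeneric("associationTable", function(object) standardGeneric("associationTable"))
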