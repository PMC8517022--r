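#' Average-resample a fine covariate raster to the analysis grid
#'
#' Each coarse cell is the mean of the fine cells it covers (NA-aware;
#' an all-NA block stays NA). The fine grid must tile the target grid by an
#' integer factor.
#'
#' @param fine numeric matrix.
#' @param targetDims c(rows, cols) of the analysis grid.
#' @return numeric matrix of the target shape.
#' @export
resampleCovariate <- function(fine, targetDims) {
  fr <- nrow(fine) / targetDims[1]
  fc <- ncol(fine) / targetDims[2]
  if (fr < 1 || fc < 1 || fr != round(fr) || fc != round(fc))
    stop("fine grid does not cover the target grid by an integer factor")
  if (fr != fc) stop("anisotropic resampling factors are not supported")
  blockMean(fine, as.integer(fr))
}

#' Decile (quantile) classes of a covariate
#'
#' Class boundaries are the covariate's quantiles over the valid domain
#' pixels, giving roughly equal pixel counts per class. Heavily tied values
#' can collapse boundaries; collapsed classes are merged with a warning.
#'
#' @param covariate numeric matrix (NA = outside domain).
#' @param nClasses number of classes (10 = deciles).
#' @return list with \code{breaks}, \code{classOf} (integer matrix of class
#'   labels 1..nClasses, NA outside the domain), and \code{nClasses}
#'   (effective count after merging).
#' @export
quantileClasses <- function(covariate, nClasses = 10) {
  v <- covariate[!is.na(covariate)]
  if (length(unique(v)) < nClasses)
    stop("need at least nClasses distinct values")
  br <- stats::quantile(v, probs = seq(0, 1, length.out = nClasses + 1),
                        type = 7, names = FALSE)
  ubr <- unique(br)
  if (length(ubr) < length(br)) {
    warning("tied quantile boundaries: classes merged")
    br <- ubr
  }
  cls <- matrix(NA_integer_, nrow(covariate), ncol(covariate))
  ok <- !is.na(covariate)
  cls[ok] <- findInterval(covariate[ok], br, rightmost.closed = TRUE,
                          all.inside = TRUE)
  list(breaks = br, classOf = cls, nClasses = length(br) - 1L)
}

#' Bootstrap test of spatial association with a covariate
#'
#' Compares the observed count of presence pixels per covariate quantile
#' class against the empirical null distribution obtained by sampling the
#' same number of uniformly random locations over the domain (with
#' replacement), repeated \code{B} times. A class is significant at the 5\%
#' level when the observed count falls outside the (0.025, 0.975) quantiles
#' of its null counts. \code{proportion_pct} is
#' 100 * observed / (observed + null mean): values away from 50\% indicate
#' over- or under-representation.
#'
#' @param presenceMask logical matrix of presence pixels.
#' @param classes result of \code{\link{quantileClasses}} on the covariate.
#' @param B bootstrap replicates; B = 1 gives a degenerate interval equal to
#'   the single replicate (warned).
#' @param seed RNG seed.
#' @param ciProbs percentile bounds of the null interval.
#' @param domainMask logical matrix delimiting the sampling domain; default:
#'   every classified pixel.
#' @return an \code{\linkS4class{AssociationResult}}.
#' @export
bootstrapAssociation <- function(presenceMask, classes, B = 100, seed = 1L,
                                 ciProbs = c(0.025, 0.975),
                                 domainMask = NULL) {
  cls <- classes$classOf
  K <- classes$nClasses
  if (is.null(domainMask)) domainMask <- !is.na(cls)
  domainIdx <- which(domainMask & !is.na(cls))
  if (length(domainIdx) == 0) stop("empty domain")
  presIdx <- which(presenceMask & domainMask & !is.na(cls))
  N <- length(presIdx)
  if (N < 1) stop("no presence pixels in the domain")
  if (B < 1) stop("B must be >= 1")
  if (B == 1) warning("B = 1: the null interval degenerates to one replicate")

  tabCount <- function(idx) tabulate(cls[idx], nbins = K)
  observed <- tabCount(presIdx)

  set.seed(seed)
  nullCounts <- matrix(0L, B, K)
  for (b in seq_len(B)) {
    smp <- domainIdx[sample.int(length(domainIdx), N, replace = TRUE)]
    nullCounts[b, ] <- tabCount(smp)
  }
  nullMean <- colMeans(nullCounts)
  ci <- apply(nullCounts, 2, stats::quantile, probs = ciProbs, names = FALSE)
  tb <- data.frame(
    class = seq_len(K),
    lower = classes$breaks[seq_len(K)],
    upper = classes$breaks[seq_len(K) + 1],
    observed = observed,
    null_mean = nullMean,
    ci_low = ci[1, ], ci_high = ci[2, ],
    significant = observed < ci[1, ] | observed > ci[2, ],
    proportion_pct = 100 * observed / (observed + nullMean))
  new("AssociationResult", table = tb, B = as.integer(B),
      nPresence = as.integer(N), ciProbs = ciProbs, seed = as.integer(seed))
}
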