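#' Lossless integer raster I/O (TIFF)
#'
#' Writes an integer matrix as a single-band 8- or 16-bit TIFF and reads it
#' back bit-exactly. NA cells are written as the \code{nodata} value and
#' restored on read.
#'
#' @param grid integer matrix (values within the bit depth).
#' @param path file path.
#' @param bits 8 or 16.
#' @param nodata integer value standing for NA (stored in a sidecar flag).
#' @export
writeBandTiff <- function(grid, path, bits = 16, nodata = NULL) {
  stopifnot(bits %in% c(8, 16))
  top <- 2^bits - 1
  g <- grid
  hasNA <- anyNA(g)
  if (hasNA) {
    if (is.null(nodata)) nodata <- top
    g[is.na(g)] <- nodata
  }
  if (any(g < 0 | g > top)) stop(sprintf("values outside [0, %d]", top))
  tiff::writeTIFF(g / top, path, bits.per.sample = bits)
  if (hasNA) writeLines(as.character(nodata), paste0(path, ".nodata"))
  invisible(path)
}

#' @rdname writeBandTiff
#' @return \code{readBandTiff}: the integer matrix, with nodata back as NA.
#' @export
readBandTiff <- function(path) {
  if (!file.exists(path)) stop("cannot read raster: ", path)
  g <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(g)) != 2) stop("expected a single-band raster: ", path)
  nodataFile <- paste0(path, ".nodata")
  if (file.exists(nodataFile)) {
    nodata <- as.integer(readLines(nodataFile)[1])
    g[g == nodata] <- NA_integer_
  }
  g
}

#' Scene I/O: one TIFF page per band plus masks and a text sidecar
#'
#' A \code{SceneStack} is stored as a five/six-page TIFF (red, green, blue,
#' nir, cloud mask, nodata mask) with a plain-text sidecar carrying the
#' date, bit depth and cell size. Round-trips are bit-exact.
#'
#' @param scene a \code{\linkS4class{SceneStack}}.
#' @param path TIFF path; the sidecar is \code{path.meta}.
#' @export
writeScene <- function(scene, path) {
  bits <- if (scene@bitDepth == 8) 8 else 16
  top <- 2^bits - 1
  pages <- c(sceneBands(scene),
             list(cloud = matrix(as.integer(scene@cloudMask),
                                 nrow(scene@cloudMask)),
                  nodata = matrix(as.integer(scene@nodataMask),
                                  nrow(scene@nodataMask))))
  tiff::writeTIFF(lapply(pages, function(m) m / top), path,
                  bits.per.sample = bits)
  writeLines(c(paste0("date=", format(scene@date)),
               paste0("bitDepth=", scene@bitDepth)),
             paste0(path, ".meta"))
  invisible(path)
}

#' @rdname writeScene
#' @return \code{readScene}: the restored \code{SceneStack}.
#' @export
readScene <- function(path) {
  if (!file.exists(path)) stop("cannot read scene: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (length(pages) != 6) stop("expected 6 pages (4 bands + 2 masks): ", path)
  meta <- readLines(paste0(path, ".meta"))
  getv <- function(key) sub(paste0(key, "="), "",
                            grep(paste0("^", key, "="), meta, value = TRUE))
  SceneStack(pages[[1]], pages[[2]], pages[[3]], pages[[4]],
             date = as.Date(getv("date")),
             cloudMask = pages[[5]] > 0, nodataMask = pages[[6]] > 0,
             bitDepth = as.numeric(getv("bitDepth")))
}
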