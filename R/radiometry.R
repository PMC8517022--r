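#' Select scenes by cloud cover and season
#'
#' Keeps a scene when its cloud fraction is below 0.80; outside the flowering
#' months the threshold tightens to 0.25. The default flowering set is
#' December through June (the complement of July--November).
#'
#' @param scenes list of \code{\linkS4class{SceneStack}} objects.
#' @param floweringMonths integer months treated as the flowering season.
#' @param maxCloud,maxCloudOffSeason the two cloud-fraction thresholds.
#' @return the filtered list, in the original order.
#' @export
selectScenes <- function(scenes, floweringMonths = c(12, 1:6),
                         maxCloud = 0.80, maxCloudOffSeason = 0.25) {
  keep <- vapply(scenes, function(s) {
    cf <- cloudFraction(s)
    m <- as.integer(strftime(s@date, "%m"))
    lim <- if (m %in% floweringMonths) maxCloud else maxCloudOffSeason
    !is.na(cf) && cf < lim
  }, logical(1))
  scenes[keep]
}

#' Convert 12-bit reflectance to 8 bits (0--254)
#'
#' Red, green and blue: the value is capped at 2540, divided by 10 and
#' floored. Near infrared: the value is first divided by 3.937 (scaling the
#' full 0--10000 range into 0--2540), then capped, divided by 10 and floored.
#' Monotone non-decreasing in the input.
#'
#' @param value integer reflectance values, >= 0 (vectorised).
#' @param bandKind \code{"rgb"} or \code{"nir"}.
#' @return integer values in 0--254.
#' @export
convertTo8Bit <- function(value, bandKind = c("rgb", "nir")) {
  bandKind <- match.arg(bandKind)
  if (any(value < 0, na.rm = TRUE)) stop("reflectance values must be >= 0")
  v <- if (bandKind == "nir") value / 3.937 else value
  as.integer(floor(pmin(2540, v) / 10))
}

#' Convert a whole scene to 8 bits
#'
#' @param scene a 12-bit \code{\linkS4class{SceneStack}}.
#' @return an 8-bit \code{\linkS4class{SceneStack}} with the same masks.
#' @export
convertSceneTo8Bit <- function(scene) {
  stopifnot(scene@bitDepth == 12)
  dims <- dim(scene@red)
  asBand <- function(v) matrix(v, dims[1], dims[2])
  SceneStack(asBand(convertTo8Bit(scene@red, "rgb")),
             asBand(convertTo8Bit(scene@green, "rgb")),
             asBand(convertTo8Bit(scene@blue, "rgb")),
             asBand(convertTo8Bit(scene@nir, "nir")),
             date = scene@date, cloudMask = scene@cloudMask,
             nodataMask = scene@nodataMask, bitDepth = 8)
}

#' Tile a scene into overlapping patches
#'
#' Pads the scene with nodata (value 0) to the next multiple of the core
#' size, then cuts a regular grid of cores extended by \code{border} pixels
#' on each side (out-of-image extension filled with 0). With the defaults the
#' native 10240-pixel scene yields 80 x 80 patches of 136 x 136 pixels whose
#' 128 x 128 cores tile the padded image exactly once.
#'
#' @param scene an 8-bit \code{\linkS4class{SceneStack}}.
#' @param core core side in pixels (one analysis cell).
#' @param border overlap margin added on each side.
#' @return list of patches, each a list with \code{pixels} (side x side x 4
#'   array), \code{gridRow}, \code{gridCol} (0-based); attributes
#'   \code{gridDims} and \code{paddedSide} describe the grid.
#' @export
tileScene <- function(scene, core = 128L, border = 4L) {
  b <- sceneBands(scene)
  H <- nrow(b$red); W <- ncol(b$red)
  if (H == 0 || W == 0) stop("empty scene")
  padH <- ceiling(H / core) * core
  padW <- ceiling(W / core) * core
  stack <- array(0, dim = c(padH, padW, 4))
  for (k in 1:4) stack[1:H, 1:W, k] <- b[[k]]
  nR <- padH / core; nC <- padW / core
  side <- core + 2 * border
  patches <- vector("list", nR * nC)
  i <- 0
  for (r in 0:(nR - 1)) {
    for (c in 0:(nC - 1)) {
      px <- array(0, dim = c(side, side, 4))
      r0 <- r * core - border; c0 <- c * core - border   # 0-based, half-open
      rIn <- max(0, r0):min(padH - 1, r0 + side - 1)
      cIn <- max(0, c0):min(padW - 1, c0 + side - 1)
      px[rIn - r0 + 1, cIn - c0 + 1, ] <- stack[rIn + 1, cIn + 1, ]
      i <- i + 1
      patches[[i]] <- list(pixels = px, gridRow = r, gridCol = c)
    }
  }
  attr(patches, "gridDims") <- c(nR, nC)
  attr(patches, "core") <- core
  attr(patches, "border") <- border
  attr(patches, "paddedSide") <- c(padH, padW)
  patches
}

#' Reassemble patch cores into the padded scene
#'
#' Inverse of \code{\link{tileScene}} restricted to the cores: stitching the
#' central \code{core x core} windows back reproduces the padded image
#' bit-exactly.
#'
#' @param patches the list returned by \code{\link{tileScene}}.
#' @return a paddedH x paddedW x 4 array.
#' @export
reassemblePatches <- function(patches) {
  gd <- attr(patches, "gridDims")
  core <- attr(patches, "core")
  border <- attr(patches, "border")
  pad <- attr(patches, "paddedSide")
  out <- array(0, dim = c(pad[1], pad[2], 4))
  idx <- (border + 1):(border + core)
  for (p in patches) {
    ri <- p$gridRow * core + seq_len(core)
    ci <- p$gridCol * core + seq_len(core)
    out[ri, ci, ] <- p$pixels[idx, idx, ]
  }
  out
}
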