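#' Configuration of a synthetic study world
#'
#' Bundles every knob of the synthetic-world generator. The defaults emulate
#' the study system: clumped blooming stands on a coarse analysis grid of
#' 1280 m cells, population peak days spread over the austral flowering
#' season (December--April, centred near the March equinox), episode
#' durations around 80 days, presence odds increasing with elevation, slope
#' and tree cover, and spatially correlated cloud cover.
#'
#' @param gridRows,gridCols presence-grid size in cells (1280 m each).
#' @param patchPixels image pixels per cell side when rendering scenes.
#' @param nPopulations number of phenological populations (>= 0).
#' @param peakDays per-population peak day-of-year (1--365); default evenly
#'   spread over days 340..105 (December to mid-April, circularly).
#' @param durationDays per-population flowering duration in days (> 0).
#' @param amplitude per-population bloom amplitude in (0, 1].
#' @param centerSpread spatial SD of each population's extent, in cell units.
#' @param backgroundFraction baseline presence probability per cell.
#' @param cloudProb per-scene expected cloud-covered fraction, in [0, 1].
#' @param covariateLink named coefficients (log-odds per SD) tying presence
#'   probability to elevation, slope and treecover.
#' @param twoPeakFraction fraction of presence pixels assigned to a second
#'   population (two flowering peaks), when more than one population exists.
#' @param magentaContrast additive 12-bit offset applied to the red and blue
#'   bands of a fully blooming stand.
#' @param visibilityThreshold bloom intensity below which a stand is too
#'   sparse to shift the cell's reflectance (and so cannot be detected).
#' @param noiseSd per-pixel radiometric noise SD (12-bit counts).
#' @param seed integer RNG seed; identical seed + config gives a
#'   bit-identical world.
#' @return a named list of class \code{worldConfig}.
#' @export
worldConfig <- function(gridRows = 50, gridCols = 50, patchPixels = 128,
                        nPopulations = 3, peakDays = NULL,
                        durationDays = 80, amplitude = 0.9,
                        centerSpread = NULL,
                        backgroundFraction = 0.1, cloudProb = 0.3,
                        covariateLink = c(elevation = 1, slope = 0.5,
                                          treecover = 0.5),
                        twoPeakFraction = 0.2,
                        magentaContrast = 3000, visibilityThreshold = 0.3,
                        noiseSd = 40, seed = 1L) {
  if (gridRows < 1 || gridCols < 1) stop("grid dimensions must be positive")
  if (nPopulations < 0) stop("nPopulations must be >= 0")
  if (backgroundFraction < 0 || backgroundFraction > 1 ||
      cloudProb < 0 || cloudProb > 1 || twoPeakFraction < 0 ||
      twoPeakFraction > 1)
    stop("probabilities must lie in [0, 1]")
  if (nPopulations > 0) {
    if (is.null(peakDays)) {
      ## December through mid-April, wrapped across the year boundary
      peakDays <- wrapDay(seq(340, 340 + 130, length.out = nPopulations))
    }
    peakDays <- rep_len(peakDays, nPopulations)
    if (any(peakDays < 1 | peakDays > 365))
      stop("peakDays must lie in [1, 365]")
    durationDays <- rep_len(durationDays, nPopulations)
    if (any(durationDays <= 0)) stop("durationDays must be positive")
    amplitude <- rep_len(amplitude, nPopulations)
    if (any(amplitude <= 0 | amplitude > 1))
      stop("amplitude must lie in (0, 1]")
  }
  if (is.null(centerSpread)) centerSpread <- min(gridRows, gridCols) / 6
  structure(list(
    gridRows = as.integer(gridRows), gridCols = as.integer(gridCols),
    patchPixels = as.integer(patchPixels),
    nPopulations = as.integer(nPopulations), peakDays = peakDays,
    durationDays = durationDays, amplitude = amplitude,
    centerSpread = centerSpread,
    backgroundFraction = backgroundFraction, cloudProb = cloudProb,
    covariateLink = covariateLink, twoPeakFraction = twoPeakFraction,
    magentaContrast = magentaContrast,
    visibilityThreshold = visibilityThreshold,
    noiseSd = noiseSd, seed = as.integer(seed)), class = "worldConfig")
}

## Six environmental covariate grids with the qualitative structure of the
## study region: elevation as a smooth field, slope as its gradient,
## orographic precipitation, temperature decreasing with elevation.
makeCovariates <- function(rows, cols) {
  elevField <- smoothField(rows, cols)
  elevation <- rescaleField(elevField, 0, 2000)
  dzdr <- rbind(diff(elevation), rep(0, cols))
  dzdc <- cbind(t(apply(elevation, 1, diff)), rep(0, rows))
  cellm <- 1280
  slope <- atan(sqrt(dzdr^2 + dzdc^2) / cellm) * 180 / pi
  treecover <- rescaleField(0.6 * elevField + 0.8 * smoothField(rows, cols),
                            0, 100)
  precipitation <- rescaleField(0.5 * elevField + smoothField(rows, cols),
                                800, 2200)
  tmin <- rescaleField(-elevField + 0.3 * smoothField(rows, cols), 12, 21)
  tmax <- tmin + rescaleField(0.2 * smoothField(rows, cols), 6, 9)
  list(elevation = elevation, slope = slope, treecover = treecover,
       precipitation = precipitation, tmin = tmin, tmax = tmax)
}

#' Generate a synthetic ground-truth world
#'
#' Draws the presence grid (probability increasing under the configured
#' covariate link, exactly \code{backgroundFraction} when all link
#' coefficients are zero), assigns each presence pixel to a spatially clumped
#' phenological population (and, for a configurable fraction, to a second
#' one, giving two flowering peaks), and records the full truth table.
#' With \code{nPopulations = 0} there is nothing that can bloom, so the
#' presence grid is empty.
#'
#' @param config a \code{\link{worldConfig}}.
#' @return a \code{\linkS4class{SyntheticWorld}}.
#' @export
generateWorld <- function(config) {
  stopifnot(inherits(config, "worldConfig"))
  set.seed(config$seed)
  rows <- config$gridRows; cols <- config$gridCols
  covs <- makeCovariates(rows, cols)

  emptyTruth <- data.frame(row = integer(), col = integer(),
                           population = integer(), amplitude = numeric(),
                           peak_day = numeric(), duration_days = numeric(),
                           start_day = numeric(), end_day = numeric())
  emptyPops <- data.frame(population = integer(), center_row = numeric(),
                          center_col = numeric(), spread = numeric(),
                          peak_day = numeric(), duration_days = numeric(),
                          amplitude = numeric())
  if (config$nPopulations == 0) {
    return(new("SyntheticWorld",
               presence = matrix(FALSE, rows, cols), phenologyTruth = emptyTruth,
               covariates = covs, populations = emptyPops, config = unclass(config)))
  }

  link <- config$covariateLink
  eta <- stats::qlogis(min(max(config$backgroundFraction, 1e-12), 1 - 1e-12))
  for (nm in names(link)) {
    if (link[[nm]] == 0) next
    z <- covs[[nm]]
    z <- (z - mean(z)) / stats::sd(z)
    eta <- eta + link[[nm]] * z
  }
  p <- stats::plogis(eta)
  if (all(link == 0)) p <- matrix(config$backgroundFraction, rows, cols)
  pres <- matrix(stats::runif(rows * cols) < p, rows, cols)

  pops <- data.frame(
    population = seq_len(config$nPopulations),
    center_row = stats::runif(config$nPopulations, 1, rows),
    center_col = stats::runif(config$nPopulations, 1, cols),
    spread = config$centerSpread,
    peak_day = config$peakDays,
    duration_days = config$durationDays,
    amplitude = config$amplitude)

  idx <- which(pres, arr.ind = TRUE)
  truth <- emptyTruth
  if (nrow(idx) > 0) {
    pickPop <- function(r, c, exclude = 0L) {
      w <- exp(-0.5 * ((pops$center_row - r)^2 + (pops$center_col - c)^2) /
                 pops$spread^2)
      w[exclude] <- 0
      if (sum(w) <= 0) w <- rep(1, nrow(pops)) * (seq_len(nrow(pops)) != exclude)
      sample.int(nrow(pops), 1, prob = w)
    }
    rowsList <- vector("list", nrow(idx))
    for (i in seq_len(nrow(idx))) {
      r <- idx[i, 1]; c <- idx[i, 2]
      k <- pickPop(r, c)
      ks <- k
      if (config$nPopulations >= 2 &&
          stats::runif(1) < config$twoPeakFraction) {
        ks <- c(k, pickPop(r, c, exclude = k))
      }
      rowsList[[i]] <- data.frame(
        row = r, col = c, population = ks,
        amplitude = pops$amplitude[ks], peak_day = pops$peak_day[ks],
        duration_days = pops$duration_days[ks],
        start_day = wrapDay(pops$peak_day[ks] - pops$duration_days[ks] / 2),
        end_day = wrapDay(pops$peak_day[ks] + pops$duration_days[ks] / 2),
        row.names = NULL)
    }
    truth <- do.call(rbind, rowsList)
  }
  new("SyntheticWorld", presence = pres, phenologyTruth = truth,
      covariates = covs, populations = pops, config = unclass(config))
}

#' Ground-truth bloom intensity
#'
#' The truth seasonal signal of one flowering episode: a scaled Gaussian bump
#' in day-of-year centred on \code{peak_day} with SD \code{duration_days/4},
#' wrapped circularly across the year boundary.
#'
#' @param day day-of-year (vectorised).
#' @param peakDay,durationDays,amplitude episode parameters.
#' @return bloom intensity in [0, amplitude].
#' @export
bloomIntensity <- function(day, peakDay, durationDays, amplitude = 1) {
  sd <- durationDays / 4
  amplitude * exp(-0.5 * (circDayDist(day, peakDay) / sd)^2)
}

## Per-pixel truth intensity on a date: max over the pixel's episodes.
worldIntensity <- function(world, day) {
  out <- matrix(0, nrow(world@presence), ncol(world@presence))
  tt <- world@phenologyTruth
  if (nrow(tt) == 0) return(out)
  val <- bloomIntensity(day, tt$peak_day, tt$duration_days, tt$amplitude)
  for (i in seq_len(nrow(tt)))
    out[tt$row[i], tt$col[i]] <- max(out[tt$row[i], tt$col[i]], val[i])
  out
}

#' Cells currently blooming visibly on a date
#'
#' A cell counts as visibly blooming when its truth bloom intensity reaches
#' the configured visibility threshold -- sparser flowering does not shift
#' the 10 m reflectance of the stand and cannot be detected.
#'
#' @param world a \code{\linkS4class{SyntheticWorld}}.
#' @param day day-of-year.
#' @param threshold intensity threshold; default from the world config.
#' @return logical matrix.
#' @export
currentlyBlooming <- function(world, day, threshold = NULL) {
  threshold <- threshold %||% world@config$visibilityThreshold
  worldIntensity(world, day) >= threshold
}

## Spatially correlated cloud mask with exact cover fraction.
makeCloudMask <- function(rows, cols, cloudProb) {
  if (cloudProb <= 0) return(matrix(FALSE, rows, cols))
  if (cloudProb >= 1) return(matrix(TRUE, rows, cols))
  f <- smoothField(rows, cols, range = max(3, round(min(rows, cols) / 8)))
  f >= stats::quantile(f, 1 - cloudProb, type = 7)
}

#' Render a synthetic four-band scene for one date
#'
#' Paints a green-dominant forest background, raises the red and blue bands
#' over clumped blobs inside visibly blooming cells proportionally to the
#' truth intensity (the magenta signature), optionally adds pink-soil
#' confounder rectangles (high red but blue at the green level, so they do
#' not mimic the magenta signature), and overlays a bright, flagged cloud
#' mask. Values are integers in [0, 10000] (12-bit reflectance).
#'
#' @param world a \code{\linkS4class{SyntheticWorld}}.
#' @param date a \code{Date} or day-of-year number.
#' @param seed integer seed for noise, clouds and confounders.
#' @param cloudProb overrides the config cloud fraction.
#' @param noiseSd overrides the config radiometric noise SD.
#' @param nSoilPatches number of pink-soil confounder rectangles.
#' @return a 12-bit \code{\linkS4class{SceneStack}}.
#' @export
renderScene <- function(world, date, seed = 1L, cloudProb = NULL,
                        noiseSd = NULL, nSoilPatches = 3) {
  cfg <- world@config
  cloudProb <- cloudProb %||% cfg$cloudProb
  noiseSd <- noiseSd %||% cfg$noiseSd
  if (inherits(date, "Date")) {
    day <- as.integer(strftime(date, "%j"))
    day <- min(day, DAYS_PER_YEAR)
  } else {
    day <- wrapDay(date)
    date <- as.Date(day - 1, origin = "2018-01-01")
  }
  set.seed(seed)
  px <- cfg$patchPixels
  H <- nrow(world@presence) * px; W <- ncol(world@presence) * px
  base <- c(red = 700, green = 1200, blue = 600, nir = 3000)
  bands <- lapply(base, function(mu) {
    matrix(mu + if (noiseSd > 0) stats::rnorm(H * W, sd = noiseSd) else 0, H, W)
  })

  ## pink-soil confounders: red well above green, blue at green level
  if (nSoilPatches > 0) {
    for (i in seq_len(nSoilPatches)) {
      h <- sample(3:max(3, px %/% 3), 1); w <- sample(3:max(3, px %/% 3), 1)
      r0 <- sample.int(H - h, 1); c0 <- sample.int(W - w, 1)
      ri <- r0:(r0 + h - 1); ci <- c0:(c0 + w - 1)
      bands$red[ri, ci] <- bands$red[ri, ci] + 900
      bands$green[ri, ci] <- bands$green[ri, ci] - 150
      bands$blue[ri, ci] <- bands$blue[ri, ci] + 580
      bands$nir[ri, ci] <- bands$nir[ri, ci] - 800
    }
  }

  ## magenta blobs in visibly blooming cells
  inten <- worldIntensity(world, day)
  vis <- inten >= cfg$visibilityThreshold
  if (any(vis)) {
    blobR <- max(2, round(0.35 * px))
    ctr <- (px + 1) / 2
    dd <- outer((seq_len(px) - ctr)^2, (seq_len(px) - ctr)^2, "+")
    blob <- dd <= blobR^2
    for (ij in which(vis)) {
      r <- (ij - 1) %% nrow(vis) + 1; c <- (ij - 1) %/% nrow(vis) + 1
      ri <- ((r - 1) * px + 1):(r * px); ci <- ((c - 1) * px + 1):(c * px)
      off <- cfg$magentaContrast * inten[r, c] * blob
      bands$red[ri, ci] <- bands$red[ri, ci] + off
      bands$blue[ri, ci] <- bands$blue[ri, ci] + off
    }
  }

  cloud <- makeCloudMask(H, W, cloudProb)
  if (any(cloud)) for (b in names(bands)) bands[[b]][cloud] <- 9000

  bands <- lapply(bands, function(m) {
    matrix(as.integer(pmin(10000, pmax(0, round(m)))), H, W)
  })
  SceneStack(bands$red, bands$green, bands$blue, bands$nir, date = date,
             cloudMask = cloud, bitDepth = 12)
}

#' Simulate per-pixel dated observation states directly
#'
#' Bypasses the imagery: for each grid pixel and date, the pixel is cloud
#' with probability \code{cloudProb}; otherwise, if the truth bloom
#' intensity reaches the visibility threshold, it is detected with
#' probability \code{pDetect}, else clear. This is the generating process
#' the detection-mapping and phenology stages invert.
#'
#' @param world a \code{\linkS4class{SyntheticWorld}}.
#' @param dates \code{Date} vector (or day-of-year numbers) of observations.
#' @param pDetect detection probability for a visibly blooming pixel.
#' @param cloudProb per-pixel per-date cloud probability.
#' @param seed integer RNG seed.
#' @param threshold visibility threshold; default from the world config.
#' @return an \code{\linkS4class{ObservationSeries}}.
#' @export
simulateObservations <- function(world, dates, pDetect = 0.95,
                                 cloudProb = NULL, seed = 1L,
                                 threshold = NULL) {
  if (length(dates) == 0) stop("empty date list")
  if (pDetect < 0 || pDetect > 1) stop("pDetect must lie in [0, 1]")
  cloudProb <- cloudProb %||% world@config$cloudProb
  threshold <- threshold %||% world@config$visibilityThreshold
  if (!inherits(dates, "Date")) {
    dates <- as.Date(wrapDay(dates) - 1, origin = "2018-01-01")
  }
  set.seed(seed)
  rows <- nrow(world@presence); cols <- ncol(world@presence)
  states <- array(STATE_CLEAR, dim = c(rows, cols, length(dates)))
  days <- as.integer(strftime(dates, "%j"))
  days[days > DAYS_PER_YEAR] <- DAYS_PER_YEAR
  for (i in seq_along(dates)) {
    vis <- worldIntensity(world, days[i]) >= threshold
    cl <- matrix(stats::runif(rows * cols) < cloudProb, rows, cols)
    det <- vis & !cl &
      matrix(stats::runif(rows * cols) < pDetect, rows, cols)
    st <- matrix(STATE_CLEAR, rows, cols)
    st[det] <- STATE_DETECTED
    st[cl] <- STATE_CLOUD
    states[, , i] <- st
  }
  new("ObservationSeries", states = states, dates = dates)
}
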