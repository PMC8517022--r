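#' Pipeline configuration
#'
#' Collects every stage parameter of the end-to-end run. All stochastic
#' stages derive their seeds from the single \code{seed}.
#'
#' @param outputDir artifact directory (created if absent).
#' @param seed global integer seed.
#' @param world a \code{\link{worldConfig}}.
#' @param nScenes number of rendered scenes.
#' @param sceneStart first acquisition date.
#' @param sceneIntervalDays days between acquisitions (30 = roughly monthly).
#' @param detector a \code{\link{detectorConfig}} (its \code{inputSide} is
#'   derived from the world's cell size plus the tiling border).
#' @param border tiling overlap margin in pixels.
#' @param trainScenes number of scenes whose patches feed the training set.
#' @param maxTrainPatches cap on the training-set size.
#' @param minDetections detection floor for maps and phenology.
#' @param k,kMax cluster count (NULL = elbow) and elbow scan limit.
#' @param B bootstrap replicates for the association test.
#' @param verbose print stage progress.
#' @return a named list of class \code{pipelineConfig}.
#' @export
pipelineConfig <- function(outputDir, seed = 1L, world = worldConfig(),
                           nScenes = 48, sceneStart = "2016-07-01",
                           sceneIntervalDays = 30,
                           detector = detectorConfig(),
                           border = 4L, trainScenes = 6,
                           maxTrainPatches = 500, minDetections = 4,
                           k = NULL, kMax = 8, B = 100, verbose = TRUE) {
  structure(list(outputDir = outputDir, seed = as.integer(seed),
                 world = world, nScenes = as.integer(nScenes),
                 sceneStart = as.Date(sceneStart),
                 sceneIntervalDays = sceneIntervalDays,
                 detector = detector, border = as.integer(border),
                 trainScenes = as.integer(trainScenes),
                 maxTrainPatches = as.integer(maxTrainPatches),
                 minDetections = minDetections, k = k, kMax = kMax,
                 B = as.integer(B), verbose = verbose),
            class = "pipelineConfig")
}

#' Demo configuration: a small world the full pipeline crosses in minutes
#'
#' A 20 x 20 cell world rendered at 32 pixels per cell, 48 roughly monthly
#' scenes over four years, and a two-block detector.
#'
#' @param outputDir artifact directory.
#' @param seed global seed.
#' @return a \code{\link{pipelineConfig}}.
#' @export
demoConfig <- function(outputDir = file.path(tempdir(), "bloomsat-demo"),
                       seed = 1L) {
  pipelineConfig(
    outputDir = outputDir, seed = seed,
    world = worldConfig(gridRows = 20, gridCols = 20, patchPixels = 32,
                        nPopulations = 3, cloudProb = 0.25, seed = seed),
    nScenes = 48, sceneIntervalDays = 30,
    detector = detectorConfig(nBlocks = 2, filtersPerBlock = c(8, 16),
                              denseUnits = 32, dropoutRate = 0.3,
                              learningRate = 1e-3, batchSize = 32,
                              epochs = 12, inputSide = 40, seed = seed),
    trainScenes = 6, maxTrainPatches = 400, kMax = 6, B = 100)
}

#' Load a pipeline configuration from a YAML file
#'
#' Top-level keys mirror the \code{\link{pipelineConfig}} arguments; the
#' \code{world} and \code{detector} sections mirror \code{\link{worldConfig}}
#' and \code{\link{detectorConfig}}.
#'
#' @param path YAML file.
#' @param overrides named list applied on top of the file values.
#' @return a \code{\link{pipelineConfig}}.
#' @export
loadPipelineConfig <- function(path, overrides = list()) {
  y <- yaml::read_yaml(path)
  y <- utils::modifyList(y, overrides)
  wc <- do.call(worldConfig, y$world %||% list())
  dc <- do.call(detectorConfig, y$detector %||% list())
  y$world <- wc; y$detector <- dc
  do.call(pipelineConfig, y)
}

stageDirs <- function(cfg) {
  root <- cfg$outputDir
  list(root = root,
       simulate = file.path(root, "world"),
       preprocess = file.path(root, "scenes8"),
       train = file.path(root, "model"),
       detect = file.path(root, "detections"),
       map = file.path(root, "map"),
       phenology = file.path(root, "phenology"),
       cluster = file.path(root, "cluster"),
       associate = file.path(root, "association"))
}

manifestKey <- function(params, inputs) {
  as.character(jsonlite::toJSON(
    list(params = params, inputs = as.list(tools::md5sum(inputs))),
    auto_unbox = TRUE, digits = NA))
}

writeManifest <- function(dir, stage, params, inputs = character(0)) {
  m <- list(stage = stage, key = manifestKey(params, inputs),
            files = list.files(dir))
  jsonlite::write_json(m, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

manifestCurrent <- function(dir, stage, params, inputs = character(0)) {
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf)) return(FALSE)
  old <- tryCatch(jsonlite::read_json(mf), error = function(e) NULL)
  if (is.null(old) || is.null(old$key)) return(FALSE)
  identical(manifestKey(params, inputs), old$key)
}

requireStage <- function(path, stage) {
  if (!file.exists(path))
    stop(sprintf("missing upstream artifact '%s': run stage '%s' first",
                 path, stage), call. = FALSE)
}

writeGridCsv <- function(m, path) {
  utils::write.table(m, path, sep = ",", row.names = FALSE, col.names = FALSE)
}
readGridCsv <- function(path) {
  as.matrix(utils::read.table(path, sep = ","))
}

#' Run the pipeline
#'
#' Executes the requested stages in dependency order (simulate, preprocess,
#' train, detect, map, phenology, cluster, associate). Each stage writes its
#' artifacts plus a manifest recording its parameters and input checksums;
#' a stage whose manifest already matches is skipped unless \code{force}.
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @param stages subset of stage names; default all.
#' @param force re-run stages even when their manifests are current.
#' @return (invisibly) the list of stage directories.
#' @export
runPipeline <- function(config,
                        stages = c("simulate", "preprocess", "train",
                                   "detect", "map", "phenology",
                                   "cluster", "associate"),
                        force = FALSE) {
  stopifnot(inherits(config, "pipelineConfig"))
  order <- c("simulate", "preprocess", "train", "detect", "map",
             "phenology", "cluster", "associate")
  stages <- order[order %in% stages]
  dirs <- stageDirs(config)
  for (d in dirs) dir.create(d, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (config$verbose) message(sprintf(...))
  t0 <- Sys.time()
  for (st in stages) {
    fun <- get(paste0("stage_", st), mode = "function")
    s0 <- Sys.time()
    ran <- fun(config, dirs, force)
    say("[%s] %s (%.1f s, seed %d)", st,
        if (ran) "done" else "up to date",
        as.numeric(difftime(Sys.time(), s0, units = "secs")), config$seed)
  }
  say("pipeline finished in %.1f s",
      as.numeric(difftime(Sys.time(), t0, units = "secs")))
  invisible(dirs)
}

sceneDatesOf <- function(cfg) {
  cfg$sceneStart + round(seq(0, by = cfg$sceneIntervalDays,
                             length.out = cfg$nScenes))
}

stage_simulate <- function(cfg, dirs, force) {
  d <- dirs$simulate
  params <- list(world = unclass(cfg$world), nScenes = cfg$nScenes,
                 intervalDays = cfg$sceneIntervalDays,
                 start = format(cfg$sceneStart), seed = cfg$seed)
  if (!force && manifestCurrent(d, "simulate", params)) return(FALSE)
  world <- generateWorld(cfg$world)
  utils::write.csv(phenologyTruth(world), file.path(d, "truth.csv"),
                   row.names = FALSE)
  utils::write.csv(worldPopulations(world), file.path(d, "populations.csv"),
                   row.names = FALSE)
  writeGridCsv(presence(world) * 1L, file.path(d, "presence.csv"))
  for (nm in names(covariates(world)))
    writeGridCsv(covariates(world)[[nm]],
                 file.path(d, paste0("covariate_", nm, ".csv")))
  dates <- sceneDatesOf(cfg)
  files <- character(length(dates))
  for (i in seq_along(dates)) {
    sc <- renderScene(world, dates[i], seed = cfg$seed + i)
    files[i] <- file.path(d, sprintf("scene_%03d.tif", i))
    writeScene(sc, files[i])
  }
  utils::write.csv(data.frame(file = basename(files), date = format(dates)),
                   file.path(d, "scene_dates.csv"), row.names = FALSE)
  writeManifest(d, "simulate", params)
  TRUE
}

stage_preprocess <- function(cfg, dirs, force) {
  d <- dirs$preprocess
  idx <- file.path(dirs$simulate, "scene_dates.csv")
  requireStage(idx, "simulate")
  params <- list(seed = cfg$seed)
  if (!force && manifestCurrent(d, "preprocess", params, idx)) return(FALSE)
  tab <- utils::read.csv(idx)
  kept <- data.frame(file = character(), date = character())
  for (i in seq_len(nrow(tab))) {
    sc <- readScene(file.path(dirs$simulate, tab$file[i]))
    if (length(selectScenes(list(sc))) == 0) next
    sc8 <- convertSceneTo8Bit(sc)
    writeScene(sc8, file.path(d, tab$file[i]))
    kept <- rbind(kept, tab[i, ])
  }
  utils::write.csv(kept, file.path(d, "scene_dates.csv"), row.names = FALSE)
  writeManifest(d, "preprocess", params, idx)
  TRUE
}

## Oracle-labelled patch sample from the first training scenes
collectTrainingPatches <- function(cfg, dirs) {
  tab <- utils::read.csv(file.path(dirs$preprocess, "scene_dates.csv"))
  core <- cfg$world$patchPixels
  patches <- list(); labels <- integer(0)
  for (i in seq_len(min(cfg$trainScenes, nrow(tab)))) {
    sc <- readScene(file.path(dirs$preprocess, tab$file[i]))
    pt <- tileScene(sc, core = core, border = cfg$border)
    lb <- vapply(pt, referenceColorDetector, integer(1), border = cfg$border)
    patches <- c(patches, lapply(pt, `[[`, "pixels"))
    labels <- c(labels, lb)
  }
  ## balance-aware subsample
  set.seed(cfg$seed)
  pos <- which(labels == 1); neg <- which(labels == 0)
  nPos <- min(length(pos), cfg$maxTrainPatches %/% 2)
  nNeg <- min(length(neg), cfg$maxTrainPatches - nPos)
  keep <- c(sample(pos, nPos), sample(neg, nNeg))
  list(patches = patches[keep], labels = labels[keep])
}

stage_train <- function(cfg, dirs, force) {
  d <- dirs$train
  idx <- file.path(dirs$preprocess, "scene_dates.csv")
  requireStage(idx, "preprocess")
  params <- list(detector = unclass(cfg$detector), border = cfg$border,
                 trainScenes = cfg$trainScenes,
                 maxTrainPatches = cfg$maxTrainPatches, seed = cfg$seed)
  if (!force && manifestCurrent(d, "train", params, idx)) return(FALSE)
  tr <- collectTrainingPatches(cfg, dirs)
  dcfg <- cfg$detector
  dcfg$inputSide <- cfg$world$patchPixels + 2L * cfg$border
  model <- buildDetector(dcfg)
  res <- trainDetector(model, tr$patches, tr$labels, dcfg)
  saveRDS(res$model, file.path(d, "model.rds"))
  utils::write.csv(res$history, file.path(d, "history.csv"), row.names = FALSE)
  writeManifest(d, "train", params, idx)
  TRUE
}

stage_detect <- function(cfg, dirs, force) {
  d <- dirs$detect
  modelFile <- file.path(dirs$train, "model.rds")
  idx <- file.path(dirs$preprocess, "scene_dates.csv")
  requireStage(modelFile, "train")
  requireStage(idx, "preprocess")
  params <- list(border = cfg$border, seed = cfg$seed)
  if (!force && manifestCurrent(d, "detect", params, c(modelFile, idx)))
    return(FALSE)
  model <- readRDS(modelFile)
  tab <- utils::read.csv(idx)
  core <- cfg$world$patchPixels
  rowsList <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    sc <- readScene(file.path(dirs$preprocess, tab$file[i]))
    pt <- tileScene(sc, core = core, border = cfg$border)
    pred <- predictPatches(model, pt)
    gd <- attr(pt, "gridDims")
    pres <- spatializePredictions(pred, gd)
    cf <- cellCloudFraction(sceneCloudMask(sc), core)
    rowsList[[i]] <- data.frame(
      date = tab$date[i],
      row = rep(seq_len(gd[1]), times = gd[2]),
      col = rep(seq_len(gd[2]), each = gd[1]),
      presence = as.integer(pres), cloud_frac = as.numeric(cf))
  }
  utils::write.csv(do.call(rbind, rowsList),
                   file.path(d, "detections.csv"), row.names = FALSE)
  writeManifest(d, "detect", params, c(modelFile, idx))
  TRUE
}

stage_map <- function(cfg, dirs, force) {
  d <- dirs$map
  det <- file.path(dirs$detect, "detections.csv")
  requireStage(det, "detect")
  params <- list(minDetections = cfg$minDetections)
  if (!force && manifestCurrent(d, "map", params, det)) return(FALSE)
  tab <- utils::read.csv(det)
  dates <- sort(unique(as.Date(tab$date)))
  nR <- max(tab$row); nC <- max(tab$col)
  presenceList <- list(); cloudList <- list(); sceneDates <- as.Date(character())
  for (dt in as.list(dates)) {
    sub <- tab[tab$date == format(dt), ]
    pm <- matrix(0L, nR, nC); cm <- matrix(0, nR, nC)
    pm[cbind(sub$row, sub$col)] <- sub$presence
    cm[cbind(sub$row, sub$col)] <- sub$cloud_frac
    presenceList <- c(presenceList, list(pm))
    cloudList <- c(cloudList, list(cm))
    sceneDates <- c(sceneDates, dt)
  }
  obs <- accumulateDailyStates(presenceList, cloudList, sceneDates)
  saveRDS(obs, file.path(d, "observations.rds"))
  fm <- frequencyMap(obs, minDetections = cfg$minDetections)
  writeGridCsv(frequencyPct(fm), file.path(d, "frequency_pct.csv"))
  cnt <- detectionCounts(fm)
  for (nm in names(cnt))
    writeGridCsv(cnt[[nm]], file.path(d, paste0("n_", nm, ".csv")))
  jsonlite::write_json(summaryStats(fm), file.path(d, "stats.json"),
                       auto_unbox = TRUE, digits = NA)
  writeManifest(d, "map", params, det)
  TRUE
}

stage_phenology <- function(cfg, dirs, force) {
  d <- dirs$phenology
  obsFile <- file.path(dirs$map, "observations.rds")
  requireStage(obsFile, "map")
  params <- list(minDetections = cfg$minDetections)
  if (!force && manifestCurrent(d, "phenology", params, obsFile)) return(FALSE)
  obs <- readRDS(obsFile)
  st <- obsStates(obs); dates <- obsDates(obs)
  nR <- dim(st)[1]; nC <- dim(st)[2]
  fits <- list(); events <- list()
  for (r in seq_len(nR)) for (c in seq_len(nC)) {
    px <- fitPixelPhenology(st[r, c, ], dates,
                            minDetections = cfg$minDetections)
    if (is.null(px) || nrow(px$events) == 0) next
    pid <- (c - 1L) * nR + r
    fits[[length(fits) + 1L]] <- data.frame(
      pixel_id = pid, t(bloomParams(px$fit)),
      weighted_r2 = weightedR2(px$fit))
    ev <- px$events
    ev$start_value <- px$daily[ev$start_day]
    ev$end_value <- px$daily[ev$end_day]
    ev <- cbind(pixel_id = pid, row = r, col = c, ev)
    events[[length(events) + 1L]] <- ev
  }
  fitsTab <- if (length(fits)) do.call(rbind, fits) else data.frame()
  evTab <- if (length(events)) do.call(rbind, events) else data.frame()
  utils::write.csv(fitsTab, file.path(d, "fits.csv"), row.names = FALSE)
  utils::write.csv(evTab, file.path(d, "events.csv"), row.names = FALSE)
  writeManifest(d, "phenology", params, obsFile)
  TRUE
}

stage_cluster <- function(cfg, dirs, force) {
  d <- dirs$cluster
  evFile <- file.path(dirs$phenology, "events.csv")
  requireStage(evFile, "phenology")
  params <- list(k = cfg$k, kMax = cfg$kMax, seed = cfg$seed)
  if (!force && manifestCurrent(d, "cluster", params, evFile)) return(FALSE)
  ev <- utils::read.csv(evFile)
  if (nrow(ev) == 0) stop("no flowering events to cluster")
  cellM <- 1280
  coords <- data.frame(pixel_id = ev$pixel_id,
                       x = (ev$col - 0.5) * cellM,
                       y = (ev$row - 0.5) * cellM)
  coords <- coords[!duplicated(coords$pixel_id), ]
  rows <- buildFeatureTable(ev, coords)
  cm <- clusterPopulations(rows, k = cfg$k, kMax = cfg$kMax, seed = cfg$seed)
  utils::write.csv(cbind(rows, cluster = assignments(cm)),
                   file.path(d, "assignments.csv"), row.names = FALSE)
  utils::write.csv(clusterSummary(cm), file.path(d, "summary.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(k = seq_along(withinSS(cm)),
                              within_ss = withinSS(cm)),
                   file.path(d, "within_ss.csv"), row.names = FALSE)
  writeManifest(d, "cluster", params, evFile)
  TRUE
}

stage_associate <- function(cfg, dirs, force) {
  d <- dirs$associate
  detFile <- file.path(dirs$map, "n_detected.csv")
  requireStage(detFile, "map")
  params <- list(B = cfg$B, minDetections = cfg$minDetections,
                 seed = cfg$seed)
  if (!force && manifestCurrent(d, "associate", params, detFile)) return(FALSE)
  nDet <- readGridCsv(detFile)
  presenceMask <- nDet >= cfg$minDetections
  out <- list()
  for (nm in c("elevation", "slope", "treecover", "precipitation",
               "tmin", "tmax")) {
    cov <- readGridCsv(file.path(dirs$simulate,
                                 paste0("covariate_", nm, ".csv")))
    cov <- resampleCovariate(cov, dim(presenceMask))
    qc <- quantileClasses(cov)
    ar <- bootstrapAssociation(presenceMask, qc, B = cfg$B,
                               seed = cfg$seed)
    out[[nm]] <- cbind(covariate = nm, associationTable(ar))
  }
  utils::write.csv(do.call(rbind, out), file.path(d, "association.csv"),
                   row.names = FALSE)
  writeManifest(d, "associate", params, detFile)
  TRUE
}
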