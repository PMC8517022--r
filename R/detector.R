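#' Detector configuration
#'
#' Parameters of the patch-presence classifier: a VGG-style encoder of
#' convolution + max-pooling blocks, one fully connected layer, dropout,
#' and a 2-unit softmax giving the probability that the patch contains a
#' blooming stand. The per-block filter counts double from a configurable
#' base by default.
#'
#' @param nBlocks number of convolution + pooling blocks (>= 1).
#' @param filtersPerBlock integer vector of length \code{nBlocks}; default
#'   \code{baseFilters * 2^(0:(nBlocks-1))}.
#' @param baseFilters filter count of the first block.
#' @param denseUnits units of the fully connected layer.
#' @param dropoutRate dropout after the dense layer.
#' @param learningRate RMSprop learning rate.
#' @param batchSize minibatch size.
#' @param epochs maximum training epochs.
#' @param classWeightRatio weight of the bloom class relative to background
#'   (background weight 1); \code{NULL} means computed from the data as
#'   n_background / n_bloom.
#' @param weightLoss apply the class weights to the loss as well as to the
#'   accuracy metric.
#' @param inputSide patch side length in pixels.
#' @param seed RNG seed for initialisation, shuffling and dropout.
#' @return a named list of class \code{detectorConfig}.
#' @export
detectorConfig <- function(nBlocks = 5, filtersPerBlock = NULL,
                           baseFilters = 16, denseUnits = 100,
                           dropoutRate = 0.5, learningRate = 1e-4,
                           batchSize = 32, epochs = 50,
                           classWeightRatio = NULL, weightLoss = TRUE,
                           inputSide = 136, seed = 1L) {
  if (nBlocks < 1) stop("nBlocks must be >= 1")
  if (learningRate <= 0) stop("learningRate must be positive")
  if (is.null(filtersPerBlock))
    filtersPerBlock <- baseFilters * 2^(0:(nBlocks - 1))
  if (length(filtersPerBlock) != nBlocks)
    stop("filtersPerBlock must have one entry per block")
  if (!is.null(classWeightRatio) && classWeightRatio <= 0)
    stop("classWeightRatio must be positive")
  structure(list(nBlocks = as.integer(nBlocks),
                 filtersPerBlock = as.integer(filtersPerBlock),
                 denseUnits = as.integer(denseUnits),
                 dropoutRate = dropoutRate, learningRate = learningRate,
                 batchSize = as.integer(batchSize),
                 epochs = as.integer(epochs),
                 classWeightRatio = classWeightRatio,
                 weightLoss = weightLoss,
                 inputSide = as.integer(inputSide),
                 seed = as.integer(seed)),
            class = "detectorConfig")
}

#' Class-weight ratio for imbalanced training sets
#'
#' The bloom class weight is the ratio of background to bloom examples;
#' the background weight stays 1.
#'
#' @param nBackground,nBloom class counts.
#' @return the ratio (numeric).
#' @export
classWeightRatio <- function(nBackground, nBloom) {
  if (nBloom <= 0) stop("need at least one bloom example")
  nBackground / nBloom
}

#' Build an untrained detector
#'
#' Initialises the encoder (He-scaled weights), reports parameter counts,
#' and checks that the input side survives the pooling depth. Any side
#' >= 2^nBlocks is accepted (odd intermediate sizes drop the trailing
#' row/column at pooling, as is conventional).
#'
#' @param config a \code{\link{detectorConfig}}.
#' @param inputChannels number of image bands.
#' @return a model object (list) with elements \code{nParams} and
#'   \code{nTrainable}.
#' @export
buildDetector <- function(config, inputChannels = 4L) {
  stopifnot(inherits(config, "detectorConfig"))
  side <- config$inputSide
  if (side < 2^config$nBlocks)
    stop(sprintf("input side %d too small for %d pooling blocks",
                 side, config$nBlocks))
  set.seed(config$seed)
  conv <- vector("list", config$nBlocks)
  inCh <- inputChannels
  s <- side
  for (i in seq_len(config$nBlocks)) {
    outCh <- config$filtersPerBlock[i]
    fanIn <- 9 * inCh
    conv[[i]] <- list(
      W = matrix(stats::rnorm(fanIn * outCh, sd = sqrt(2 / fanIn)),
                 fanIn, outCh),
      b = rep(0, outCh))
    inCh <- outCh
    s <- s %/% 2
  }
  nFlat <- s * s * inCh
  dense1 <- list(W = matrix(stats::rnorm(nFlat * config$denseUnits,
                                         sd = sqrt(2 / nFlat)),
                            nFlat, config$denseUnits),
                 b = rep(0, config$denseUnits))
  dense2 <- list(W = matrix(stats::rnorm(config$denseUnits * 2,
                                         sd = sqrt(2 / config$denseUnits)),
                            config$denseUnits, 2),
                 b = rep(0, 2))
  nConv <- sum(vapply(conv, function(l) length(l$W) + length(l$b), numeric(1)))
  nParams <- nConv + length(dense1$W) + length(dense1$b) +
    length(dense2$W) + length(dense2$b)
  structure(list(conv = conv, dense1 = dense1, dense2 = dense2,
                 dropoutRate = config$dropoutRate, inputSide = side,
                 inputChannels = inputChannels, config = config,
                 nParams = nParams, nTrainable = nParams),
            class = "bloomDetector")
}

#' @export
print.bloomDetector <- function(x, ...) {
  cat(sprintf("bloomDetector: %d blocks (%s filters), dense %d, input %dx%dx%d\n",
              x$config$nBlocks,
              paste(x$config$filtersPerBlock, collapse = "-"),
              x$config$denseUnits, x$inputSide, x$inputSide, x$inputChannels))
  cat(sprintf("  parameters: %d total, %d trainable\n", x$nParams, x$nTrainable))
  invisible(x)
}

#' Flip augmentation
#'
#' The only augmentation used: a horizontal and/or vertical flip, each drawn
#' with probability 0.5 (atmospheric and illumination variation provides the
#' rest naturally).
#'
#' @param patch an H x W x C array.
#' @param flipH,flipV force (TRUE/FALSE) a flip instead of drawing it.
#' @return the (possibly flipped) patch.
#' @export
augmentPatch <- function(patch, flipH = NULL, flipV = NULL) {
  if (is.null(flipH)) flipH <- stats::runif(1) < 0.5
  if (is.null(flipV)) flipV <- stats::runif(1) < 0.5
  if (flipH) patch <- patch[, rev(seq_len(dim(patch)[2])), , drop = FALSE]
  if (flipV) patch <- patch[rev(seq_len(dim(patch)[1])), , , drop = FALSE]
  patch
}

## Normalise 8-bit patches for the network and coerce list input.
asPatchList <- function(patches) {
  if (is.array(patches) && length(dim(patches)) == 3) patches <- list(patches)
  lapply(patches, function(p) {
    if (is.list(p) && !is.null(p$pixels)) p <- p$pixels
    p / 254
  })
}

#' Train the detector
#'
#' Minimises cross-entropy with RMSprop and per-class weights (background 1,
#' bloom \code{classWeightRatio}); the weighted-accuracy metric uses the same
#' weights. An 80/20 seeded validation split is held out, batches are
#' re-shuffled each epoch, patches are flip-augmented, and the epoch snapshot
#' with the highest validation weighted accuracy is returned.
#'
#' @param model an untrained model from \code{\link{buildDetector}}.
#' @param patches list of 8-bit H x W x C arrays (or \code{tileScene} output).
#' @param labels 0/1 vector (1 = bloom) of the same length.
#' @param config optional \code{\link{detectorConfig}} overriding the model's.
#' @return list with \code{model} (best snapshot) and \code{history}
#'   (data.frame epoch, loss, weighted_accuracy; plus \code{best_epoch} and
#'   \code{best_weighted_accuracy} attributes).
#' @export
trainDetector <- function(model, patches, labels, config = NULL) {
  config <- config %||% model$config
  x <- asPatchList(patches)
  y <- as.integer(labels) + 1L            # 1 = background, 2 = bloom
  if (length(x) != length(y)) stop("patch/label length mismatch")
  if (length(unique(y)) < 2) stop("need at least one example of each class")
  ratio <- config$classWeightRatio %||% classWeightRatio(sum(y == 1), sum(y == 2))
  wClass <- c(1, ratio)

  set.seed(config$seed)
  n <- length(x)
  idx <- sample.int(n)
  nVal <- max(1L, round(0.2 * n))
  valIdx <- idx[seq_len(nVal)]
  trIdx <- idx[-seq_len(nVal)]
  if (length(unique(y[trIdx])) < 2 || length(unique(y[valIdx])) < 2)
    stop("both classes must appear in the train and validation splits")

  state <- cnnZeroLike(model)
  history <- data.frame(epoch = integer(), loss = numeric(),
                        weighted_accuracy = numeric())
  best <- list(acc = -Inf, model = model, epoch = 0L)

  valAccuracy <- function(m) {
    num <- 0; den <- 0
    for (i in valIdx) {
      p <- cnnForward(m, x[[i]], training = FALSE)$prob
      pred <- if (p[2] >= 0.5) 2L else 1L
      w <- wClass[y[i]]
      num <- num + w * (pred == y[i])
      den <- den + w
    }
    num / den
  }

  for (epoch in seq_len(config$epochs)) {
    ord <- sample(trIdx)
    epochLoss <- 0
    for (b0 in seq(1, length(ord), by = config$batchSize)) {
      batch <- ord[b0:min(b0 + config$batchSize - 1, length(ord))]
      acc <- cnnZeroLike(model)
      for (i in batch) {
        xi <- augmentPatch(x[[i]])
        lossW <- if (config$weightLoss) wClass[y[i]] else 1
        fwd <- cnnForward(model, xi, training = TRUE)
        epochLoss <- epochLoss - lossW * log(max(fwd$prob[y[i]], 1e-12))
        acc <- cnnAccumulate(acc, cnnBackward(model, fwd, y[i], lossW))
      }
      sc <- 1 / length(batch)
      for (i in seq_along(acc$conv)) {
        acc$conv[[i]]$W <- acc$conv[[i]]$W * sc
        acc$conv[[i]]$b <- acc$conv[[i]]$b * sc
      }
      acc$dense1$W <- acc$dense1$W * sc; acc$dense1$b <- acc$dense1$b * sc
      acc$dense2$W <- acc$dense2$W * sc; acc$dense2$b <- acc$dense2$b * sc
      st <- cnnRmspropStep(model, acc, state, config$learningRate)
      model <- st$model; state <- st$state
    }
    wacc <- valAccuracy(model)
    history <- rbind(history, data.frame(
      epoch = epoch, loss = epochLoss / length(trIdx),
      weighted_accuracy = wacc))
    if (wacc > best$acc) best <- list(acc = wacc, model = model, epoch = epoch)
  }
  attr(history, "best_epoch") <- best$epoch
  attr(history, "best_weighted_accuracy") <- best$acc
  list(model = best$model, history = history)
}

#' Best epoch of a training history
#'
#' @param history the history data.frame from \code{\link{trainDetector}},
#'   or any numeric vector of per-epoch accuracies.
#' @return 1-based index of the epoch with the highest weighted accuracy.
#' @export
bestEpoch <- function(history) {
  acc <- if (is.data.frame(history)) history$weighted_accuracy else history
  which.max(acc)
}

#' Predict patch presence
#'
#' Presence is 1 when the softmax probability of the bloom class is at least
#' 0.5 (argmax of the two-class output, ties to presence). Deterministic
#' given fixed weights and independent of batch order.
#'
#' @param model a trained model.
#' @param patches list of patches (see \code{\link{trainDetector}}).
#' @param prob return the bloom-class probability instead of 0/1.
#' @return integer 0/1 vector (or numeric probabilities).
#' @export
predictPatches <- function(model, patches, prob = FALSE) {
  x <- asPatchList(patches)
  for (p in x)
    if (!identical(dim(p)[1:2], c(model$inputSide, model$inputSide)) ||
        dim(p)[3] != model$inputChannels)
      stop("patch shape does not match the model input")
  pr <- vapply(x, function(xi) cnnForward(model, xi)$prob[2], numeric(1))
  if (prob) pr else as.integer(pr >= 0.5)
}

## 4-connected component sizes of a logical mask (flood fill).
clumpSizes <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  sizes <- integer(0)
  nxt <- 0L
  for (start in which(mask & lab == 0L)) {
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    sz <- 0L
    while (length(queue)) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      sz <- sz + 1L
      r <- (cur - 1L) %% H + 1L; c <- (cur - 1L) %/% H + 1L
      nb <- c(if (r > 1) cur - 1L, if (r < H) cur + 1L,
              if (c > 1) cur - H, if (c < W) cur + H)
      nb <- nb[mask[nb] & lab[nb] == 0L]
      lab[nb] <- nxt
      queue <- c(queue, nb)
    }
    sizes[nxt] <- sz
  }
  sizes
}

#' Deterministic colour-rule reference detector
#'
#' The test oracle encoding the visual identification criteria: presence is
#' declared when a 4-connected clump of at least \code{minClump} pixels
#' inside the patch core has both red and blue exceeding green by more than
#' \code{delta} (8-bit counts). The border is ignored: labels apply to the
#' core only.
#'
#' @param patch an 8-bit H x W x C array (bands red, green, blue, ...), or a
#'   \code{tileScene} patch.
#' @param minClump minimum clump size in pixels.
#' @param delta colour contrast threshold (8-bit).
#' @param border margin excluded from the decision.
#' @return integer 0/1.
#' @export
referenceColorDetector <- function(patch, minClump = 9L, delta = 20,
                                   border = 4L) {
  if (is.list(patch) && !is.null(patch$pixels)) patch <- patch$pixels
  H <- dim(patch)[1]; W <- dim(patch)[2]
  core <- patch[(border + 1):(H - border), (border + 1):(W - border), ,
                drop = FALSE]
  mask <- core[, , 1] > core[, , 2] + delta & core[, , 3] > core[, , 2] + delta
  if (!any(mask)) return(0L)
  as.integer(any(clumpSizes(mask) >= minClump))
}
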