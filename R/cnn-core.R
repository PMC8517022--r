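## Minimal convolutional-network engine used by the patch detector.
## Single-image forward/backward passes with im2col 3 x 3 same-padding
## convolutions, 2 x 2 max pooling (odd trailing row/column dropped),
## a ReLU dense layer with inverted dropout, and a 2-unit softmax head.
## Plain R throughout: the networks this package trains are tiny.

cnnIm2col <- function(x) {
  # x: H x W x C -> (H*W) x (9*C), zero padding 1
  H <- dim(x)[1]; W <- dim(x)[2]; C <- dim(x)[3]
  xp <- array(0, dim = c(H + 2, W + 2, C))
  xp[2:(H + 1), 2:(W + 1), ] <- x
  cols <- vector("list", 9)
  i <- 0
  for (dj in 0:2) for (di in 0:2) {
    i <- i + 1
    cols[[i]] <- matrix(xp[di + seq_len(H), dj + seq_len(W), ], H * W, C)
  }
  do.call(cbind, cols)
}

cnnCol2im <- function(dX, H, W, C) {
  # inverse scatter-add of cnnIm2col
  gp <- array(0, dim = c(H + 2, W + 2, C))
  i <- 0
  for (dj in 0:2) for (di in 0:2) {
    i <- i + 1
    block <- dX[, ((i - 1) * C + 1):(i * C), drop = FALSE]
    gp[di + seq_len(H), dj + seq_len(W), ] <-
      gp[di + seq_len(H), dj + seq_len(W), ] + array(block, dim = c(H, W, C))
  }
  gp[2:(H + 1), 2:(W + 1), , drop = FALSE]
}

cnnConvForward <- function(x, layer) {
  H <- dim(x)[1]; W <- dim(x)[2]
  X <- cnnIm2col(x)
  Z <- sweep(X %*% layer$W, 2, layer$b, "+")
  A <- pmax(Z, 0)
  list(out = array(A, dim = c(H, W, ncol(layer$W))), X = X, relu = Z > 0)
}

cnnConvBackward <- function(dA, cache, layer, inDims) {
  H <- dim(dA)[1]; W <- dim(dA)[2]
  dZ <- matrix(dA, H * W, dim(dA)[3]) * cache$relu
  dW <- crossprod(cache$X, dZ)
  db <- colSums(dZ)
  dX <- dZ %*% t(layer$W)
  dx <- cnnCol2im(dX, inDims[1], inDims[2], inDims[3])
  list(dx = dx, dW = dW, db = db)
}

cnnPoolForward <- function(x) {
  H2 <- dim(x)[1] %/% 2; W2 <- dim(x)[2] %/% 2; C <- dim(x)[3]
  a11 <- x[2 * seq_len(H2) - 1, 2 * seq_len(W2) - 1, , drop = FALSE]
  a12 <- x[2 * seq_len(H2) - 1, 2 * seq_len(W2),     , drop = FALSE]
  a21 <- x[2 * seq_len(H2),     2 * seq_len(W2) - 1, , drop = FALSE]
  a22 <- x[2 * seq_len(H2),     2 * seq_len(W2),     , drop = FALSE]
  p <- pmax(a11, a12, a21, a22)
  masks <- list(a11 == p, a12 == p, a21 == p, a22 == p)
  counts <- masks[[1]] + masks[[2]] + masks[[3]] + masks[[4]]
  list(out = p, masks = masks, counts = counts, inDims = dim(x))
}

cnnPoolBackward <- function(dp, cache) {
  H2 <- dim(dp)[1]; W2 <- dim(dp)[2]
  dx <- array(0, dim = cache$inDims)
  g <- dp / cache$counts
  dx[2 * seq_len(H2) - 1, 2 * seq_len(W2) - 1, ] <- g * cache$masks[[1]]
  dx[2 * seq_len(H2) - 1, 2 * seq_len(W2),     ] <- g * cache$masks[[2]]
  dx[2 * seq_len(H2),     2 * seq_len(W2) - 1, ] <- g * cache$masks[[3]]
  dx[2 * seq_len(H2),     2 * seq_len(W2),     ] <- g * cache$masks[[4]]
  dx
}

cnnForward <- function(model, x, training = FALSE) {
  caches <- vector("list", length(model$conv))
  a <- x
  for (i in seq_along(model$conv)) {
    cv <- cnnConvForward(a, model$conv[[i]])
    pl <- cnnPoolForward(cv$out)
    caches[[i]] <- list(conv = cv, pool = pl, inDims = dim(a))
    a <- pl$out
  }
  v <- as.vector(a)
  z1 <- as.vector(crossprod(model$dense1$W, v)) + model$dense1$b
  h <- pmax(z1, 0)
  if (training && model$dropoutRate > 0) {
    keep <- stats::runif(length(h)) >= model$dropoutRate
    hDrop <- h * keep / (1 - model$dropoutRate)
  } else {
    keep <- NULL
    hDrop <- h
  }
  logits <- as.vector(crossprod(model$dense2$W, hDrop)) + model$dense2$b
  e <- exp(logits - max(logits))
  prob <- e / sum(e)
  list(prob = prob, caches = caches, v = v, poolDims = dim(a),
       relu1 = z1 > 0, h = h, hDrop = hDrop, keep = keep)
}

## Backward pass for one example; label in {1, 2} (background, bloom);
## weight scales the cross-entropy loss. Returns gradient list mirroring
## the parameter structure.
cnnBackward <- function(model, fwd, label, weight) {
  dlogits <- weight * (fwd$prob - c(label == 1, label == 2))
  g <- list(
    dense2 = list(W = outer(fwd$hDrop, dlogits), b = dlogits),
    dense1 = NULL, conv = vector("list", length(model$conv)))
  dh <- as.vector(model$dense2$W %*% dlogits)
  if (!is.null(fwd$keep)) dh <- dh * fwd$keep / (1 - model$dropoutRate)
  dz1 <- dh * fwd$relu1
  g$dense1 <- list(W = outer(fwd$v, dz1), b = dz1)
  da <- array(as.vector(model$dense1$W %*% dz1), dim = fwd$poolDims)
  for (i in rev(seq_along(model$conv))) {
    cache <- fwd$caches[[i]]
    dconvOut <- cnnPoolBackward(da, cache$pool)
    bk <- cnnConvBackward(dconvOut, cache$conv, model$conv[[i]], cache$inDims)
    g$conv[[i]] <- list(W = bk$dW, b = bk$db)
    da <- bk$dx
  }
  g
}

cnnZeroLike <- function(model) {
  list(conv = lapply(model$conv, function(l)
         list(W = l$W * 0, b = l$b * 0)),
       dense1 = list(W = model$dense1$W * 0, b = model$dense1$b * 0),
       dense2 = list(W = model$dense2$W * 0, b = model$dense2$b * 0))
}

cnnAccumulate <- function(acc, g) {
  for (i in seq_along(acc$conv)) {
    acc$conv[[i]]$W <- acc$conv[[i]]$W + g$conv[[i]]$W
    acc$conv[[i]]$b <- acc$conv[[i]]$b + g$conv[[i]]$b
  }
  acc$dense1$W <- acc$dense1$W + g$dense1$W
  acc$dense1$b <- acc$dense1$b + g$dense1$b
  acc$dense2$W <- acc$dense2$W + g$dense2$W
  acc$dense2$b <- acc$dense2$b + g$dense2$b
  acc
}

## RMSprop step (rho = 0.9), applied in place on the model parameters.
cnnRmspropStep <- function(model, grads, state, lr, rho = 0.9, eps = 1e-8) {
  upd <- function(p, g, s) {
    s <- rho * s + (1 - rho) * g^2
    list(p = p - lr * g / (sqrt(s) + eps), s = s)
  }
  for (i in seq_along(model$conv)) {
    r <- upd(model$conv[[i]]$W, grads$conv[[i]]$W, state$conv[[i]]$W)
    model$conv[[i]]$W <- r$p; state$conv[[i]]$W <- r$s
    r <- upd(model$conv[[i]]$b, grads$conv[[i]]$b, state$conv[[i]]$b)
    model$conv[[i]]$b <- r$p; state$conv[[i]]$b <- r$s
  }
  r <- upd(model$dense1$W, grads$dense1$W, state$dense1$W)
  model$dense1$W <- r$p; state$dense1$W <- r$s
  r <- upd(model$dense1$b, grads$dense1$b, state$dense1$b)
  model$dense1$b <- r$p; state$dense1$b <- r$s
  r <- upd(model$dense2$W, grads$dense2$W, state$dense2$W)
  model$dense2$W <- r$p; state$dense2$W <- r$s
  r <- upd(model$dense2$b, grads$dense2$b, state$dense2$b)
  model$dense2$b <- r$p; state$dense2$b <- r$s
  list(model = model, state = state)
}
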