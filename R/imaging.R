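#' Rectified linear unit
#'
#' The activation used after every convolutional layer of the feature
#' extractor: `relu(x) = x` for `x > 0` and `0` otherwise. Vectorized.
#'
#' @param x numeric vector/array of finite values.
#' @return `x` with negative entries replaced by 0.
#' @examples
#' relu(c(-3, 0, 2))
#' @export
relu <- function(x) {
  if (!is.numeric(x) || any(!is.finite(x)))
    stop("relu() requires finite numeric input", call. = FALSE)
  pmax(x, 0)
}

#' Configuration of the convolutional feature extractor
#'
#' Three convolutional layers (5x5 kernels, stride 1, zero padding, ReLU),
#' each followed by 2x2 max pooling with stride 2, so a 40x40 input shrinks
#' 40 -> 20 -> 10 -> 5 per side and the last layer's 8 filters yield eight
#' 5x5 maps. A flatten + 3-way softmax head is attached only for training
#' and discarded afterwards.
#'
#' @param filters integer triple: filters per conv layer (last must be 8).
#' @param inputSide input image side in pixels; must be 40 so that three
#'   2x pools end at 5x5.
#' @param learningRate Adam learning rate.
#' @param maxEpochs training epoch cap.
#' @param patience early-stopping patience (epochs without validation-loss
#'   improvement); best weights are restored.
#' @param batchSize minibatch size.
#' @param seed integer seeding weight init and shuffling.
#' @return validated list of class `ExtractorConfig`.
#' @export
extractorConfig <- function(filters = c(12L, 14L, 8L), inputSide = 40L,
                            learningRate = 5e-4, maxEpochs = 50L,
                            patience = 5L, batchSize = 32L, seed = 1L) {
  stopifnot(length(filters) == 3L, all(filters >= 1))
  if (filters[3] != 8L)
    stop("the last conv layer must have 8 filters (one per stimulation ",
         "electrode)", call. = FALSE)
  inputSide <- assertCount(inputSide, "inputSide", lower = 8L)
  if (inputSide %% 8L != 0L || inputSide / 8L != 5L)
    stop("inputSide must be 40: three 2x2 poolings must end at 5x5",
         call. = FALSE)
  cfg <- list(filters = as.integer(filters), kernel = 5L,
              inputSide = inputSide,
              learningRate = assertNumber(learningRate, "learningRate",
                                          lower = 1e-12),
              maxEpochs = assertCount(maxEpochs, "maxEpochs", lower = 0L),
              patience = assertCount(patience, "patience", lower = 1L),
              batchSize = assertCount(batchSize, "batchSize", lower = 1L),
              seed = assertCount(seed, "seed"))
  class(cfg) <- "ExtractorConfig"
  cfg
}

# ---- synthetic image fixtures -------------------------------------------

#' Generate synthetic 3-class colour images
#'
#' Stands in for a small object-image dataset (3 categories such as apples,
#' cars and cups): a filled disc, an elongated rectangle, and a
#' disc-with-handle silhouette, each with per-image colour, position and
#' scale jitter on a noisy background. Deterministic given `seed`.
#'
#' @param nPerClass images per class (>= 1).
#' @param side image side in pixels (>= 40).
#' @param seed integer seed.
#' @return list of images; each image is a list with `pixels` (side x side
#'   x 3 array in \[0, 1\]), `label` (class name) and `id`.
#' @examples
#' imgs <- generateSyntheticImages(2, seed = 1)
#' length(imgs)
#' @export
generateSyntheticImages <- function(nPerClass, side = 40L, seed = 1L) {
  nPerClass <- assertCount(nPerClass, "nPerClass", lower = 1L)
  side <- assertCount(side, "side")
  if (side < 40L)
    stop("side must be >= 40 (extractor geometry)", call. = FALSE)
  seed <- assertCount(seed, "seed")
  set.seed(tagSeed(seed, "synth-images"))

  classes <- c("disc", "bar", "handled")
  base <- list(disc = c(0.80, 0.15, 0.10), bar = c(0.15, 0.25, 0.80),
               handled = c(0.15, 0.70, 0.25))
  gx <- matrix(rep(seq(0, 1, length.out = side), side), side, side)
  gy <- t(gx)

  out <- vector("list", 3L * nPerClass)
  n <- 0L
  for (cl in classes) {
    for (j in seq_len(nPerClass)) {
      cx <- 0.5 + runif(1, -0.12, 0.12)
      cy <- 0.5 + runif(1, -0.12, 0.12)
      sc <- runif(1, 0.75, 1.15)
      col <- pmin(pmax(base[[cl]] + runif(3, -0.08, 0.08), 0), 1)
      mask <- switch(cl,
        disc = ((gx - cx)^2 + (gy - cy)^2) < (0.28 * sc)^2,
        bar = (abs(gx - cx) < 0.38 * sc) & (abs(gy - cy) < 0.12 * sc),
        handled = {
          body <- ((gx - cx)^2 + (gy - cy)^2) < (0.22 * sc)^2
          ring <- ((gx - cx - 0.26 * sc)^2 + (gy - cy)^2)
          handle <- ring < (0.14 * sc)^2 & ring > (0.07 * sc)^2
          body | handle
        })
      px <- array(0, c(side, side, 3L))
      bg <- 0.82 + matrix(rnorm(side * side, 0, 0.02), side, side)
      for (ch in 1:3) {
        plane <- bg
        plane[mask] <- col[ch] + rnorm(sum(mask), 0, 0.02)
        px[, , ch] <- plane
      }
      px <- pmin(pmax(px, 0), 1)
      n <- n + 1L
      out[[n]] <- list(pixels = px, label = cl,
                       id = sprintf("%s-%03d", cl, j))
    }
  }
  out
}

# ---- convolution plumbing -----------------------------------------------

# Linear indices into a zero-padded (H+K-1, W+K-1, C) array selecting, for
# each of the H*W output positions (column-major), the K*K*C patch values.
im2colIndex <- function(H, W, C, K) {
  Hp <- H + K - 1L
  pos <- as.matrix(expand.grid(i = seq_len(H), j = seq_len(W)))
  off <- as.matrix(expand.grid(di = 0:(K - 1L), dj = 0:(K - 1L),
                               c = 0:(C - 1L)))
  i <- outer(pos[, "i"], off[, "di"], "+")
  j <- outer(pos[, "j"], off[, "dj"], "+")
  cc <- matrix(off[, "c"], nrow(pos), nrow(off), byrow = TRUE)
  i + (j - 1L) * Hp + cc * (Hp * (W + K - 1L))
}

# Same-padding convolution of x (H,W,Cin) with kernel array (K,K,Cin,Cout).
convForward <- function(x, Wk, b, idx = NULL) {
  d <- dim(x); K <- dim(Wk)[1]
  H <- d[1]; Wd <- d[2]; Cin <- d[3]; Cout <- dim(Wk)[4]
  p <- (K - 1L) %/% 2L
  pad <- array(0, c(H + 2L * p, Wd + 2L * p, Cin))
  pad[(p + 1L):(p + H), (p + 1L):(p + Wd), ] <- x
  if (is.null(idx)) idx <- im2colIndex(H, Wd, Cin, K)
  X <- matrix(pad[idx], nrow(idx), ncol(idx))
  Y <- X %*% matrix(Wk, K * K * Cin, Cout)
  Y <- sweep(Y, 2L, b, "+")
  list(out = array(Y, c(H, Wd, Cout)), X = X, idx = idx)
}

# 2x2 max pooling with stride 2; returns pooled array and the argmax code
# (1..4, first-maximum tie-break) needed to route gradients back.
maxPool2 <- function(x) {
  d <- dim(x)
  r1 <- seq(1L, d[1], 2L); r2 <- r1 + 1L
  c1 <- seq(1L, d[2], 2L); c2 <- c1 + 1L
  cand <- list(x[r1, c1, , drop = FALSE], x[r2, c1, , drop = FALSE],
               x[r1, c2, , drop = FALSE], x[r2, c2, , drop = FALSE])
  best <- cand[[1]]
  which <- array(1L, dim(best))
  for (k in 2:4) {
    upd <- cand[[k]] > best
    best[upd] <- cand[[k]][upd]
    which[upd] <- k
  }
  list(out = best, which = which)
}

# Forward pass through the conv/pool stack. Returns activations needed for
# backprop when `keep = TRUE`.
extractorForward <- function(px, weights, keep = FALSE, cache = NULL) {
  acts <- list()
  x <- px
  for (l in seq_along(weights$conv)) {
    cf <- convForward(x, weights$conv[[l]]$W, weights$conv[[l]]$b,
                      idx = cache$idx[[l]])
    a <- relu(cf$out)
    mp <- maxPool2(a)
    if (keep)
      acts[[l]] <- list(X = cf$X, idx = cf$idx, pre = cf$out,
                        which = mp$which, inDim = dim(x))
    x <- mp$out
  }
  list(maps = x, acts = acts)
}

# Gradient of the conv/pool stack given the gradient at the final maps.
extractorBackward <- function(dmaps, weights, acts) {
  grads <- vector("list", length(weights$conv))
  dx <- dmaps
  for (l in rev(seq_along(weights$conv))) {
    a <- acts[[l]]
    preDim <- dim(a$pre)
    # un-pool: send gradient to the argmax corner of each 2x2 block
    dpre <- array(0, preDim)
    r1 <- seq(1L, preDim[1], 2L); c1 <- seq(1L, preDim[2], 2L)
    for (k in 1:4) {
      sel <- a$which == k
      if (!any(sel)) next
      ri <- if (k %in% c(2L, 4L)) r1 + 1L else r1
      ci <- if (k %in% c(3L, 4L)) c1 + 1L else c1
      blk <- array(0, dim(dx))
      blk[sel] <- dx[sel]
      dpre[ri, ci, ] <- dpre[ri, ci, ] + blk
    }
    dpre[a$pre <= 0] <- 0
    Wk <- weights$conv[[l]]$W
    K <- dim(Wk)[1]; Cin <- dim(Wk)[3]; Cout <- dim(Wk)[4]
    dY <- matrix(dpre, ncol = Cout)
    grads[[l]] <- list(W = array(t(a$X) %*% dY, dim(Wk)),
                       b = colSums(dY))
    # gradient w.r.t. the layer input via scatter-add over patch indices
    dX <- dY %*% t(matrix(Wk, K * K * Cin, Cout))
    H <- a$inDim[1]; Wd <- a$inDim[2]
    p <- (K - 1L) %/% 2L
    dpad <- array(0, c(H + 2L * p, Wd + 2L * p, Cin))
    for (col in seq_len(ncol(dX)))
      dpad[a$idx[, col]] <- dpad[a$idx[, col]] + dX[, col]
    dx <- dpad[(p + 1L):(p + H), (p + 1L):(p + Wd), , drop = FALSE]
  }
  grads
}

adamInit <- function(w) list(m = lapply(w, function(x) x * 0),
                             v = lapply(w, function(x) x * 0), t = 0L)

adamStep <- function(w, g, st, lr, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1L
  for (k in seq_along(w)) {
    st$m[[k]] <- b1 * st$m[[k]] + (1 - b1) * g[[k]]
    st$v[[k]] <- b2 * st$v[[k]] + (1 - b2) * g[[k]]^2
    mh <- st$m[[k]] / (1 - b1^st$t)
    vh <- st$v[[k]] / (1 - b2^st$t)
    w[[k]] <- w[[k]] - lr * mh / (sqrt(vh) + eps)
  }
  list(w = w, st = st)
}

# flatten parameters into a named flat list for the optimizer
flattenWeights <- function(w) {
  out <- list()
  for (l in seq_along(w$conv)) {
    out[[sprintf("W%d", l)]] <- w$conv[[l]]$W
    out[[sprintf("b%d", l)]] <- w$conv[[l]]$b
  }
  out$Wfc <- w$fc$W
  out$bfc <- w$fc$b
  out
}

unflattenWeights <- function(flat, nconv) {
  conv <- lapply(seq_len(nconv), function(l)
    list(W = flat[[sprintf("W%d", l)]], b = flat[[sprintf("b%d", l)]]))
  list(conv = conv, fc = list(W = flat$Wfc, b = flat$bfc))
}

softmaxRows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Train the convolutional feature extractor
#'
#' Fits the six-layer extractor plus a temporary flatten + 3-way softmax
#' head by minibatch Adam on the cross-entropy loss, with early stopping on
#' validation loss (best weights restored). The head's final validation
#' metrics are reported, then the head is kept only for bookkeeping; the
#' conv/pool stack becomes a fixed feature extractor.
#'
#' @param train,val lists of images as produced by
#'   [generateSyntheticImages()] (fields `pixels`, `label`).
#' @param cfg an [extractorConfig()].
#' @return list of class `ExtractorParams`: conv weights, config,
#'   `valLoss`, `valAccuracy`, `epochsRun`, `classes`.
#' @export
trainFeatureExtractor <- function(train, val, cfg = extractorConfig()) {
  stopifnot(inherits(cfg, "ExtractorConfig"))
  if (cfg$maxEpochs < 1L)
    stop("maxEpochs must be >= 1 to train the extractor", call. = FALSE)
  if (length(val) == 0L)
    stop("early stopping needs a non-empty validation set", call. = FALSE)
  labs <- vapply(train, `[[`, character(1), "label")
  classes <- sort(unique(labs))
  if (length(classes) < 2L)
    stop("training needs at least 2 classes", call. = FALSE)
  set.seed(tagSeed(cfg$seed, "train-extractor"))

  K <- cfg$kernel
  cin <- c(3L, cfg$filters[1], cfg$filters[2])
  conv <- lapply(1:3, function(l) {
    fanIn <- K * K * cin[l]
    list(W = array(rnorm(fanIn * cfg$filters[l], 0, sqrt(2 / fanIn)),
                   c(K, K, cin[l], cfg$filters[l])),
         b = numeric(cfg$filters[l]))
  })
  nFlat <- 5L * 5L * cfg$filters[3]
  fc <- list(W = matrix(rnorm(nFlat * length(classes), 0,
                              sqrt(2 / nFlat)), nFlat, length(classes)),
             b = numeric(length(classes)))
  w <- list(conv = conv, fc = fc)

  sides <- c(cfg$inputSide, cfg$inputSide / 2L, cfg$inputSide / 4L)
  cache <- list(idx = lapply(1:3, function(l)
    im2colIndex(sides[l], sides[l], cin[l], K)))

  yTrain <- match(labs, classes)
  yVal <- match(vapply(val, `[[`, character(1), "label"), classes)
  pxTrain <- lapply(train, function(im) conformImage(im$pixels,
                                                     cfg$inputSide))
  pxVal <- lapply(val, function(im) conformImage(im$pixels, cfg$inputSide))

  evalSet <- function(pxs, y) {
    loss <- 0; hits <- 0L
    for (i in seq_along(pxs)) {
      fw <- extractorForward(pxs[[i]], w, keep = FALSE, cache = cache)
      z <- drop(matrix(fw$maps, 1L) %*% w$fc$W) + w$fc$b
      p <- drop(softmaxRows(matrix(z, 1L)))
      loss <- loss - log(max(p[y[i]], 1e-12))
      hits <- hits + (which.max(p) == y[i])
    }
    list(loss = loss / length(pxs), acc = hits / length(pxs))
  }

  st <- adamInit(flattenWeights(w))
  bestLoss <- Inf; bestW <- w; bad <- 0L; epochsRun <- 0L
  for (epoch in seq_len(cfg$maxEpochs)) {
    ord <- sample.int(length(pxTrain))
    for (start in seq(1L, length(ord), cfg$batchSize)) {
      ids <- ord[start:min(start + cfg$batchSize - 1L, length(ord))]
      gAcc <- NULL
      for (i in ids) {
        fw <- extractorForward(pxTrain[[i]], w, keep = TRUE, cache = cache)
        x <- matrix(fw$maps, 1L)
        z <- drop(x %*% w$fc$W) + w$fc$b
        p <- drop(softmaxRows(matrix(z, 1L)))
        dz <- p; dz[yTrain[i]] <- dz[yTrain[i]] - 1
        gfcW <- t(x) %*% matrix(dz, 1L)
        dmaps <- array(w$fc$W %*% dz, dim(fw$maps))
        gConv <- extractorBackward(dmaps, w, fw$acts)
        g <- list()
        for (l in 1:3) {
          g[[sprintf("W%d", l)]] <- gConv[[l]]$W
          g[[sprintf("b%d", l)]] <- gConv[[l]]$b
        }
        g$Wfc <- gfcW
        g$bfc <- dz
        gAcc <- if (is.null(gAcc)) g else
          Map(`+`, gAcc, g)
      }
      gAcc <- lapply(gAcc, `/`, length(ids))
      upd <- adamStep(flattenWeights(w), gAcc, st, cfg$learningRate)
      st <- upd$st
      w <- unflattenWeights(upd$w, 3L)
    }
    vm <- evalSet(pxVal, yVal)
    epochsRun <- epoch
    if (vm$loss < bestLoss - 1e-12) {
      bestLoss <- vm$loss; bestW <- w; bad <- 0L
    } else {
      bad <- bad + 1L
      if (bad >= cfg$patience) break
    }
  }
  w <- bestW
  vm <- evalSet(pxVal, yVal)
  structure(list(conv = w$conv, fc = w$fc, config = cfg,
                 classes = classes, valLoss = vm$loss,
                 valAccuracy = vm$acc, epochsRun = epochsRun),
            class = "ExtractorParams")
}

# Bilinear resize to side x side if needed; validates range/shape.
conformImage <- function(px, side) {
  d <- dim(px)
  if (length(d) != 3L || d[3] != 3L)
    stop("an image must be an H x W x 3 array", call. = FALSE)
  if (any(!is.finite(px)) || min(px) < 0 || max(px) > 1)
    stop("image intensities must be finite and in [0, 1]", call. = FALSE)
  if (d[1] == side && d[2] == side) return(px)
  out <- array(0, c(side, side, 3L))
  xi <- seq(1, d[1], length.out = side)
  yi <- seq(1, d[2], length.out = side)
  x0 <- pmin(floor(xi), d[1] - 1L); fx <- xi - x0
  y0 <- pmin(floor(yi), d[2] - 1L); fy <- yi - y0
  for (ch in 1:3) {
    pl <- px[, , ch]
    a <- pl[x0, y0]; b <- pl[x0 + 1L, y0]
    cc <- pl[x0, y0 + 1L]; dd <- pl[x0 + 1L, y0 + 1L]
    out[, , ch] <- (1 - fx) %o% (1 - fy) * a + fx %o% (1 - fy) * b +
      (1 - fx) %o% fy * cc + fx %o% fy * dd
  }
  out
}

#' Extract the eight normalized 5x5 feature maps from an image
#'
#' Runs the fixed conv/pool stack of trained extractor parameters on an
#' image (resampled to the configured input side if needed) and min-max
#' normalizes each of the 8 final maps to \[0, 1\]; a constant map
#' normalizes to all zeros.
#'
#' @param img an image list (field `pixels`, optional `id`) or a bare
#'   H x W x 3 array.
#' @param params `ExtractorParams` from [trainFeatureExtractor()].
#' @return a [FeatureMapSet-class] object.
#' @export
extractFeatures <- function(img, params) {
  stopifnot(inherits(params, "ExtractorParams"))
  px <- if (is.list(img)) img$pixels else img
  id <- if (is.list(img)) img$id %||% "" else ""
  px <- conformImage(px, params$config$inputSide)
  fw <- extractorForward(px, list(conv = params$conv))
  maps <- fw$maps
  if (!all(dim(maps) == c(5L, 5L, 8L)))
    stop("extractor geometry mismatch: expected 5 x 5 x 8 output",
         call. = FALSE)
  for (k in 1:8) {
    m <- maps[, , k]
    rng <- max(m) - min(m)
    maps[, , k] <- if (rng > 0) (m - min(m)) / rng else m * 0
  }
  new("FeatureMapSet", maps = maps, imageId = id)
}
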