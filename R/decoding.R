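#' Decoding configuration
#'
#' Parameters of the response-feature extraction and the multinomial
#' logistic-regression fit: spikes within `blankAfterStim` of any
#' stimulation pulse are discarded (artifact blanking), each trial is
#' binned into `nWindows` windows of `windowLen` seconds per electrode,
#' PCA keeps the smallest number of components reaching
#' `pcaVarianceKept` of the variance (capped at n-1), and the logit is fit
#' by iteratively reweighted least squares with a small ridge stabilizer.
#'
#' @param blankAfterStim artifact-blanking span after each pulse, seconds.
#' @param nWindows time windows per electrode.
#' @param windowLen window length, seconds; `nWindows * windowLen` must
#'   equal the trial duration.
#' @param pcaVarianceKept fraction of variance the PCA must retain, or an
#'   integer >= 1 for a fixed component count.
#' @param ridge L2 stabilizer on non-intercept coefficients.
#' @param maxIter IRLS iteration cap.
#' @param tol convergence tolerance on the loss decrease.
#' @return validated list of class `DecodingConfig`.
#' @export
decodingConfig <- function(blankAfterStim = 0.010, nWindows = 10L,
                           windowLen = 0.200, pcaVarianceKept = 0.95,
                           ridge = 1e-6, maxIter = 100L, tol = 1e-8) {
  cfg <- list(blankAfterStim = assertNumber(blankAfterStim,
                                            "blankAfterStim", lower = 0),
              nWindows = assertCount(nWindows, "nWindows", lower = 1L),
              windowLen = assertNumber(windowLen, "windowLen",
                                       lower = 1e-9),
              pcaVarianceKept = assertNumber(pcaVarianceKept,
                                             "pcaVarianceKept",
                                             lower = 1e-9),
              ridge = assertNumber(ridge, "ridge", lower = 0),
              maxIter = assertCount(maxIter, "maxIter", lower = 1L),
              tol = assertNumber(tol, "tol", lower = 0))
  if (cfg$blankAfterStim >= cfg$windowLen)
    stop("blankAfterStim must be smaller than windowLen", call. = FALSE)
  class(cfg) <- "DecodingConfig"
  cfg
}

#' Extract the binned response-feature vector of one trial
#'
#' Removes spikes within `blankAfterStim` seconds after any stimulation
#' pulse, counts the remaining spikes per (electrode, window) over
#' `nWindows` windows of `windowLen` seconds, and concatenates the counts
#' electrode-major (channel 0's windows first).
#'
#' @param st a [SpikeEventTable-class] whose duration equals
#'   `nWindows * windowLen`.
#' @param stimOnsets pulse times of the trial's program (seconds); use 0
#'   (trial start) when no program applies.
#' @param cfg a [decodingConfig()].
#' @return numeric vector of length `nWindows * nChannels(st)`.
#' @export
extractResponseFeatures <- function(st, stimOnsets = 0,
                                    cfg = decodingConfig()) {
  stopifnot(is(st, "SpikeEventTable"), inherits(cfg, "DecodingConfig"))
  if (abs(st@duration - cfg$nWindows * cfg$windowLen) > 1e-9)
    stop("trial duration must equal nWindows * windowLen", call. = FALSE)
  ev <- spikeEvents(st)
  if (nrow(ev) && length(stimOnsets) && cfg$blankAfterStim > 0) {
    drop <- rep(FALSE, nrow(ev))
    for (tp in stimOnsets)
      drop <- drop | (ev$time >= tp & ev$time < tp + cfg$blankAfterStim)
    ev <- ev[!drop, , drop = FALSE]
  }
  nW <- cfg$nWindows
  x <- numeric(nW * st@nChannels)
  if (nrow(ev)) {
    w <- pmin(floor(ev$time / cfg$windowLen), nW - 1L)
    idx <- ev$channel * nW + w + 1L
    cnt <- tabulate(idx, nbins = length(x))
    x <- as.numeric(cnt)
  }
  x
}

# pulse onset times of a program, pooled over channels
programOnsets <- function(pp) sort(unique(unlist(pulseTimes(pp))))

#' Fit a PCA basis for response features
#'
#' Components are ordered by explained variance; the number kept is the
#' smallest reaching the configured variance fraction, capped at
#' n_samples - 1. A zero-variance dataset (e.g. a blank-control session)
#' bypasses PCA: the basis has zero components and downstream fits reduce
#' to an intercept-only (constant) predictor.
#'
#' @param X n x p matrix of feature vectors (rows = trials).
#' @param varianceKept fraction in (0, 1\] or fixed component count >= 1.
#' @return list of class `PcaBasis`: `center`, `rotation`, `varExplained`.
#' @export
pcaFit <- function(X, varianceKept = 0.95) {
  X <- as.matrix(X)
  ctr <- colMeans(X)
  Xc <- sweep(X, 2L, ctr)
  totVar <- sum(Xc^2)
  if (totVar <= 0 || nrow(X) < 2L) {
    return(structure(list(center = ctr,
                          rotation = matrix(0, ncol(X), 0L),
                          varExplained = numeric(0)),
                     class = "PcaBasis"))
  }
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  v <- pc$sdev^2
  v <- v / sum(v)
  cap <- min(nrow(X) - 1L, ncol(X), length(v))
  m <- if (varianceKept >= 1) min(as.integer(varianceKept), cap)
       else min(which(cumsum(v) >= varianceKept - 1e-12)[1], cap)
  m <- max(m, 1L)
  structure(list(center = ctr,
                 rotation = pc$rotation[, seq_len(m), drop = FALSE],
                 varExplained = v[seq_len(m)]),
            class = "PcaBasis")
}

#' Project feature vectors onto a fitted PCA basis
#'
#' @param x a feature vector or n x p matrix.
#' @param basis a `PcaBasis` from [pcaFit()].
#' @return reduced vector/matrix with one column per kept component.
#' @export
pcaTransform <- function(x, basis) {
  stopifnot(inherits(basis, "PcaBasis"))
  x <- if (is.matrix(x)) x else matrix(x, nrow = 1L)
  sweep(x, 2L, basis$center) %*% basis$rotation
}

# Cross-entropy loss of Eqs. 6-8 form with reference class k, plus ridge
# on non-intercept coefficients. beta is (k-1) x (d+1), intercept first.
multinomLoss <- function(beta, Xa, Y, ridge) {
  eta <- Xa %*% t(beta)
  z <- cbind(eta, 0)
  p <- softmaxRows(z)
  ll <- -mean(log(pmax(p[cbind(seq_len(nrow(Y)), max.col(Y))], 1e-300)))
  pen <- if (ncol(beta) > 1L) sum(beta[, -1L, drop = FALSE]^2) else 0
  ll + ridge / 2 * pen
}

multinomProbs <- function(beta, Xa) {
  softmaxRows(cbind(Xa %*% t(beta), 0))
}

multinomGrad <- function(beta, Xa, Y, ridge) {
  n <- nrow(Xa)
  p <- multinomProbs(beta, Xa)
  km1 <- nrow(beta)
  g <- (t(p[, seq_len(km1), drop = FALSE] -
            Y[, seq_len(km1), drop = FALSE]) %*% Xa) / n
  pen <- ridge * beta
  pen[, 1L] <- 0
  g + pen
}

#' Fit the multinomial logistic-regression decoder by IRLS
#'
#' Minimizes the mean cross-entropy of the softmax-with-reference-class
#' model (the last class is the reference pattern whose coefficients are
#' implicit) plus a small ridge penalty on non-intercept coefficients,
#' using damped Newton iterations (iteratively reweighted least squares
#' with step halving), so the loss trace is monotone non-increasing.
#'
#' @param X n x d matrix of (PCA-reduced) feature vectors; d = 0 is the
#'   degenerate constant-predictor case.
#' @param y class labels (factor or vector); the *last* level/class is the
#'   reference pattern.
#' @param cfg a [decodingConfig()].
#' @param basis optional `PcaBasis` recorded in the returned decoder.
#' @return a [TrainedDecoder-class].
#' @export
fitMultinomialLogit <- function(X, y, cfg = decodingConfig(),
                                basis = NULL) {
  stopifnot(inherits(cfg, "DecodingConfig"))
  X <- as.matrix(X)
  classes <- if (is.factor(y)) levels(y) else as.character(sort(unique(y)))
  if (length(classes) < 2L)
    stop("at least 2 classes are required", call. = FALSE)
  yi <- match(as.character(y), classes)
  n <- nrow(X)
  k <- length(classes)
  Y <- matrix(0, n, k)
  Y[cbind(seq_len(n), yi)] <- 1
  Xa <- cbind(1, X)
  d1 <- ncol(Xa)
  beta <- matrix(0, k - 1L, d1)
  loss <- multinomLoss(beta, Xa, Y, cfg$ridge)
  trace <- loss
  converged <- FALSE
  for (it in seq_len(cfg$maxIter)) {
    p <- multinomProbs(beta, Xa)
    g <- multinomGrad(beta, Xa, Y, cfg$ridge)
    if (sqrt(sum(g^2)) < 1e-14) { converged <- TRUE; break }
    # full Newton system over the (k-1)(d+1) coefficients
    H <- matrix(0, (k - 1L) * d1, (k - 1L) * d1)
    for (j in seq_len(k - 1L)) {
      for (l in j:(k - 1L)) {
        w <- if (j == l) p[, j] * (1 - p[, j]) else -p[, j] * p[, l]
        blk <- crossprod(Xa, Xa * w) / n
        ri <- (j - 1L) * d1 + seq_len(d1)
        ci <- (l - 1L) * d1 + seq_len(d1)
        H[ri, ci] <- blk
        H[ci, ri] <- t(blk)
      }
    }
    pen <- rep(cfg$ridge, (k - 1L) * d1)
    pen[seq(1L, (k - 1L) * d1, by = d1)] <- 0
    diag(H) <- diag(H) + pen + 1e-10
    step <- tryCatch(solve(H, as.vector(t(g))),
                     error = function(e) as.vector(t(g)))
    step <- matrix(step, k - 1L, d1, byrow = TRUE)
    # damped step: halve until the loss does not increase
    alpha <- 1
    repeat {
      cand <- beta - alpha * step
      lNew <- multinomLoss(cand, Xa, Y, cfg$ridge)
      if (lNew <= loss + 1e-15 || alpha < 1e-8) break
      alpha <- alpha / 2
    }
    if (lNew > loss) { converged <- TRUE; break }
    beta <- cand
    delta <- loss - lNew
    loss <- lNew
    trace <- c(trace, loss)
    if (delta < cfg$tol) { converged <- TRUE; break }
  }
  ctr <- if (is.null(basis)) numeric(ncol(X)) else basis$center
  rot <- if (is.null(basis)) diag(ncol(X)) else basis$rotation
  if (is.null(basis) && ncol(X) == 0L) rot <- matrix(0, 0L, 0L)
  new("TrainedDecoder", center = ctr, rotation = as.matrix(rot),
      beta = beta, classes = classes, lossTrace = trace,
      converged = converged)
}

#' Decode a raw feature vector
#'
#' Centers and projects the vector with the decoder's PCA basis, evaluates
#' the softmax-with-reference-class probabilities and returns the most
#' probable pattern (ties break to the lowest class index).
#'
#' @param decoder a [TrainedDecoder-class].
#' @param x raw feature vector(s): vector or n x p matrix on the scale the
#'   decoder was trained on (pre-PCA).
#' @return list with `class` (character vector) and `prob` (n x k matrix,
#'   rows summing to 1).
#' @export
predictDecoder <- function(decoder, x) {
  stopifnot(is(decoder, "TrainedDecoder"))
  x <- if (is.matrix(x)) x else matrix(x, nrow = 1L)
  Xr <- if (ncol(decoder@rotation) == 0L)
    matrix(0, nrow(x), 0L)
  else
    sweep(x, 2L, decoder@center) %*% decoder@rotation
  p <- multinomProbs(decoder@beta, cbind(1, Xr))
  colnames(p) <- decoder@classes
  cls <- decoder@classes[apply(p, 1L, which.max)]
  list(class = cls, prob = p)
}

#' @describeIn predictDecoder standard `predict` method.
#' @param object a [TrainedDecoder-class].
#' @param newdata raw feature vector or matrix.
#' @param ... ignored.
#' @export
setMethod("predict", "TrainedDecoder",
          function(object, newdata, ...) predictDecoder(object, newdata))

#' Run the staged train/test decoding protocol on a session
#'
#' For each training stage s (trial blocks 1-15, 16-30, 31-45): builds
#' feature vectors for that stage's 15 trials of each of the 9 stimulus
#' patterns plus the stage's spontaneous trials (10 patterns, spontaneous
#' last as the reference pattern), fits PCA + multinomial logit, and
#' evaluates on the balanced held-out post-stage test trials (5 per
#' pattern). With `pooled = TRUE` a single decoder is trained on all
#' stages' training trials and evaluated per stage.
#'
#' @param session list with `evoked` and `spontaneous` trial lists, as
#'   returned by [simulateSession()].
#' @param cfg a [decodingConfig()].
#' @param programs optional list of the 9 pulse programs, used for
#'   artifact blanking at every pulse time (trial start only if omitted).
#' @param pooled train once on all stages instead of refitting per stage.
#' @return list of class `ProtocolResult`: per-stage list with `accuracy`
#'   (percent), `confusion`, `nTest`, plus `accuracyByStage` (numeric
#'   vector, percent).
#' @export
evaluateProtocol <- function(session, cfg = decodingConfig(),
                             programs = NULL, pooled = FALSE) {
  stopifnot(is.list(session), all(c("evoked", "spontaneous") %in%
                                    names(session)))
  pooled <- assertFlag(pooled, "pooled")
  trials <- c(session$evoked, session$spontaneous)
  md <- lapply(trials, recordingMetadata)
  stim <- vapply(md, function(m) as.integer(m$stimulus %||% 0L),
                 integer(1))
  stage <- vapply(md, function(m) as.integer(m$stage %||% NA_integer_),
                  integer(1))
  testStage <- vapply(md, function(m)
    as.integer(m$testStage %||% NA_integer_), integer(1))
  classes <- c(sprintf("pattern%d", 1:9), "spontaneous")
  labels <- ifelse(stim == 0L, "spontaneous", sprintf("pattern%d", stim))

  feats <- t(vapply(seq_along(trials), function(i) {
    onsets <- if (!is.null(programs) && stim[i] > 0L)
      programOnsets(programs[[stim[i]]]) else 0
    extractResponseFeatures(trials[[i]], onsets, cfg)
  }, numeric(cfg$nWindows * nChannels(trials[[1]]))))

  fitOn <- function(idx) {
    basis <- pcaFit(feats[idx, , drop = FALSE], cfg$pcaVarianceKept)
    Xr <- pcaTransform(feats[idx, , drop = FALSE], basis)
    fitMultinomialLogit(Xr, factor(labels[idx], levels = classes), cfg,
                        basis = basis)
  }
  pooledDec <- if (pooled) fitOn(which(!is.na(stage))) else NULL

  stages <- 1:3
  res <- lapply(stages, function(s) {
    dec <- if (pooled) pooledDec else fitOn(which(stage == s))
    te <- which(testStage == s)
    pr <- predictDecoder(dec, feats[te, , drop = FALSE])
    truth <- factor(labels[te], levels = classes)
    pred <- factor(pr$class, levels = classes)
    list(accuracy = 100 * mean(pred == truth),
         confusion = table(truth = truth, predicted = pred),
         nTest = length(te))
  })
  names(res) <- sprintf("stage%d", stages)
  res$accuracyByStage <- vapply(res[1:3], `[[`, numeric(1), "accuracy")
  class(res) <- "ProtocolResult"
  res
}
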