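# Shared fixtures and independent oracles. Everything is generated in code;
# oracles are deliberately naive (loops, explicit unions) so they stay
# independent of the vectorized implementation paths they check.

randomFeatureMapSet <- function(seed) {
  set.seed(seed)
  new("FeatureMapSet", maps = array(runif(5 * 5 * 8), c(5, 5, 8)),
      imageId = sprintf("fm-%d", seed))
}

randomPrograms <- function(n = 9, seed = 1, density = 0.4) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    bits <- matrix(as.integer(runif(80) < density), 8, 10)
    pulseProgramFromMatrix(new("PulseMatrix", bits = bits,
                               slotPeriod = 0.2))
  })
}

# direct quadruple-loop same-padding convolution (single layer oracle)
naiveConv <- function(x, W, b) {
  d <- dim(x); K <- dim(W)[1]; Cout <- dim(W)[4]
  p <- (K - 1) %/% 2
  out <- array(0, c(d[1], d[2], Cout))
  for (o in seq_len(Cout)) {
    for (i in seq_len(d[1])) {
      for (j in seq_len(d[2])) {
        acc <- b[o]
        for (ci in seq_len(d[3])) {
          for (di in seq_len(K)) {
            for (dj in seq_len(K)) {
              ii <- i + di - 1 - p
              jj <- j + dj - 1 - p
              if (ii >= 1 && ii <= d[1] && jj >= 1 && jj <= d[2])
                acc <- acc + x[ii, jj, ci] * W[di, dj, ci, o]
            }
          }
        }
        out[i, j, o] <- acc
      }
    }
  }
  out
}

# explicit interval-union tile fraction: merge one interval at a time
naiveTileFraction <- function(t, dt, recLen) {
  if (!length(t)) return(0)
  iv <- lapply(sort(t), function(ti) c(max(ti - dt, 0), min(ti + dt, recLen)))
  merged <- list(iv[[1]])
  for (k in seq_along(iv)[-1]) {
    lastIv <- merged[[length(merged)]]
    if (iv[[k]][1] <= lastIv[2])
      merged[[length(merged)]] <- c(lastIv[1], max(lastIv[2], iv[[k]][2]))
    else merged <- c(merged, list(iv[[k]]))
  }
  sum(vapply(merged, function(m) m[2] - m[1], numeric(1))) / recLen
}

# O(n*m) proximity fraction
naiveProp <- function(a, b, dt) {
  if (!length(a) || !length(b)) return(0)
  mean(vapply(a, function(ai) any(abs(ai - b) <= dt), logical(1)))
}

naiveSttc <- function(a, b, recLen, dt) {
  tA <- naiveTileFraction(a, dt, recLen)
  tB <- naiveTileFraction(b, dt, recLen)
  pA <- naiveProp(a, b, dt)
  pB <- naiveProp(b, a, dt)
  0.5 * ((pA - tB) / (1 - pA * tB) + (pB - tA) / (1 - pB * tA))
}

# cross-entropy + ridge objective written independently for oracle checks;
# beta given as a flat vector, (k-1) x (d+1) row-wise
oracleMultinomLoss <- function(betaVec, X, y, k, ridge) {
  d1 <- ncol(X) + 1
  beta <- matrix(betaVec, k - 1, d1, byrow = TRUE)
  Xa <- cbind(1, X)
  n <- nrow(Xa)
  ll <- 0
  for (i in seq_len(n)) {
    eta <- as.vector(beta %*% Xa[i, ])
    denom <- 1 + sum(exp(eta))
    p <- if (y[i] < k) exp(eta[y[i]]) / denom else 1 / denom
    ll <- ll - log(p)
  }
  ll / n + ridge / 2 * sum(beta[, -1]^2)
}

adjustedRand <- function(a, b) {
  tab <- table(a, b)
  nij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  n2 <- choose(sum(tab), 2)
  exp0 <- ai * bj / n2
  (nij - exp0) / ((ai + bj) / 2 - exp0)
}

# small clique-union adjacency for module tests
cliqueGraph <- function(sizes, weight = 0.5) {
  n <- sum(sizes)
  A <- matrix(0, n, n)
  start <- cumsum(c(1, sizes))
  for (m in seq_along(sizes)) {
    ix <- start[m]:(start[m + 1] - 1)
    A[ix, ix] <- 1
  }
  diag(A) <- 0
  new("ConnectivityGraph", nodes = seq_len(n) - 1L,
      coords = cbind(seq_len(n), 0), adjacency = A, weights = A * weight,
      partition = integer(0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
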