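mkTrial <- function(channel, time, nCh = 4L) {
  bnncode:::makeEventTable(channel, time, nCh, 2)
}

test_that("response features bin and blank spikes as specified", {
  cfg <- decodingConfig()
  x <- extractResponseFeatures(mkTrial(0L, 0.35), stimOnsets = 0, cfg)
  expect_length(x, 40)
  expect_equal(x[2], 1)                 # window index 1 (0-based)
  expect_equal(sum(x), 1)

  # a spike 5 ms after a pulse is an artifact and must be discarded
  x2 <- extractResponseFeatures(mkTrial(0L, 0.005), stimOnsets = 0, cfg)
  expect_equal(sum(x2), 0)
  x3 <- extractResponseFeatures(mkTrial(0L, 0.005), stimOnsets = 0.4, cfg)
  expect_equal(sum(x3), 1)

  empty <- extractResponseFeatures(mkTrial(integer(0), numeric(0)),
                                   stimOnsets = 0, cfg)
  expect_equal(empty, numeric(40))

  bad <- bnncode:::makeEventTable(integer(0), numeric(0), 4L, 1.9)
  expect_error(extractResponseFeatures(bad, 0, cfg), "duration")
})

test_that("PCA keeps the right subspace and survives degeneracy", {
  set.seed(10)
  z <- matrix(rnorm(200), 100, 2)
  X <- z %*% matrix(rnorm(20), 2, 10)   # exact 2-D plane in 10-D
  basis <- pcaFit(X, 0.9999)
  expect_equal(ncol(basis$rotation), 2)
  expect_gte(sum(basis$varExplained), 0.9999)

  # reconstruction error equals the discarded variance
  Xn <- X + matrix(rnorm(1000, 0, 0.05), 100)
  b2 <- pcaFit(Xn, 2)
  S <- pcaTransform(Xn, b2)
  rec <- sweep(S %*% t(b2$rotation), 2, b2$center, "+")
  totalSS <- sum(sweep(Xn, 2, colMeans(Xn))^2)
  keptSS <- sum(S^2)
  expect_equal(sum((Xn - rec)^2), totalSS - keptSS, tolerance = 1e-8)

  flat <- pcaFit(matrix(1, 20, 5))
  expect_equal(ncol(flat$rotation), 0)
  expect_equal(dim(pcaTransform(matrix(1, 3, 5), flat)), c(3L, 0L))
})

test_that("IRLS separates well-separated classes and normalizes probabilities", {
  set.seed(12)
  n <- 50
  X <- rbind(matrix(rnorm(2 * n, -3, 0.5), n, 2),
             matrix(rnorm(2 * n, 3, 0.5), n, 2))
  y <- factor(rep(c("a", "b"), each = n))
  dec <- fitMultinomialLogit(X, y)
  pr <- predictDecoder(dec, X)
  expect_equal(mean(pr$class == as.character(y)), 1)
  expect_true(all(abs(rowSums(pr$prob) - 1) < 1e-12))
  expect_true(all(diff(dec@lossTrace) <= 1e-15))   # monotone loss

  expect_error(fitMultinomialLogit(X, factor(rep("a", 2 * n))),
               "2 classes")
})

test_that("the IRLS optimum matches independent oracles", {
  set.seed(13)
  n <- 60
  X <- rbind(matrix(rnorm(3 * n / 3, -1), n / 3, 3),
             matrix(rnorm(3 * n / 3, 0), n / 3, 3),
             matrix(rnorm(3 * n / 3, 1.5), n / 3, 3))
  y <- rep(1:3, each = n / 3)
  cfg <- decodingConfig(ridge = 1e-4, tol = 1e-12, maxIter = 200L)
  dec <- fitMultinomialLogit(X, y, cfg)
  lossFit <- tail(dec@lossTrace, 1)

  # generic convex optimizer on the independently written objective
  k <- 3
  opt <- optim(rep(0, (k - 1) * 4), oracleMultinomLoss, X = X, y = y,
               k = k, ridge = 1e-4, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-15))
  expect_lt(abs(lossFit - opt$value), 1e-8)

  # numeric gradient at the fitted coefficients is ~0
  betaVec <- as.vector(t(dec@beta))
  h <- 1e-6
  g <- vapply(seq_along(betaVec), function(j) {
    e <- betaVec; e[j] <- e[j] + h
    f1 <- oracleMultinomLoss(e, X, y, k, 1e-4)
    e[j] <- e[j] - 2 * h
    f0 <- oracleMultinomLoss(e, X, y, k, 1e-4)
    (f1 - f0) / (2 * h)
  }, numeric(1))
  expect_lt(sqrt(sum(g^2)), 1e-6)
})

test_that("prediction follows the softmax geometry", {
  dec <- new("TrainedDecoder", center = numeric(2), rotation = diag(2),
             beta = matrix(0, 2, 3), classes = c("a", "b", "c"),
             lossTrace = 1, converged = TRUE)
  pr <- predictDecoder(dec, c(5, -2))
  expect_equal(as.vector(pr$prob), rep(1 / 3, 3))
  expect_equal(pr$class, "a")           # tie-break to the lowest index

  dec2 <- new("TrainedDecoder", center = numeric(2), rotation = diag(2),
              beta = rbind(c(0, 1, 0), c(0, 0, 1)), classes =
                c("a", "b", "c"), lossTrace = 1, converged = TRUE)
  x0 <- c(0.3, -0.1)
  p0 <- predictDecoder(dec2, x0)$prob[1, "a"]
  p1 <- predictDecoder(dec2, x0 + 2 * c(1, 0))$prob[1, "a"]
  expect_gt(p1, p0)                     # moving along beta_a raises P(a)
})

test_that("permuted labels drop accuracy to chance", {
  set.seed(14)
  n <- 40
  X <- rbind(matrix(rnorm(2 * n, -3, 0.5), n, 2),
             matrix(rnorm(2 * n, 3, 0.5), n, 2))
  y <- rep(c("a", "b"), each = n)
  test <- c(seq_len(10), n + seq_len(10))
  accs <- vapply(1:20, function(s) {
    set.seed(100 + s)
    yp <- sample(y[-test])
    dec <- fitMultinomialLogit(X[-test, ], factor(yp, levels = c("a", "b")))
    mean(predictDecoder(dec, X[test, ])$class == y[test])
  }, numeric(1))
  expect_lt(abs(mean(accs) - 0.5), 0.15)
})

test_that("the staged protocol scores a blank session at exactly chance", {
  progs <- randomPrograms(9, seed = 15)
  cfg <- simulatorConfig(nChannels = 16L)
  ses <- simulateSession(progs, cfg, seed = 16, blank = TRUE)
  res <- evaluateProtocol(ses, decodingConfig(), programs = progs)
  expect_equal(unname(res$accuracyByStage), c(10, 10, 10))
  expect_equal(res$stage1$nTest, 50)
})
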