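test_that("STTC is 1 on identical trains, symmetric and bounded", {
  t1 <- c(0.5, 1.2, 3.4, 7.7)
  expect_equal(sttc(t1, t1, recordingLength = 100), 1)
  set.seed(20)
  for (r in 1:20) {
    a <- sort(runif(rpois(1, 30), 0, 30))
    b <- sort(runif(rpois(1, 30), 0, 30))
    if (!length(a) || !length(b)) next
    ab <- sttc(a, b, 30)
    expect_equal(ab, sttc(b, a, 30), tolerance = 1e-12)
    expect_gte(ab, -1)
    expect_lte(ab, 1)
  }
  expect_warning(v <- sttc(numeric(0), t1, 10), "empty")
  expect_equal(v, 0)
})

test_that("tiling computation matches the interval-union brute force", {
  set.seed(21)
  for (r in 1:15) {
    a <- sort(runif(sample(1:10, 1), 0, 5))
    b <- sort(runif(sample(1:10, 1), 0, 5))
    dt <- sample(c(0.05, 0.2), 1)  # tiles can never cover the recording
    expect_equal(sttc(a, b, 5, dt), naiveSttc(a, b, 5, dt),
                 tolerance = 1e-12)
    expect_equal(bnncode:::tileLength(a, dt, 5) / 5,
                 naiveTileFraction(a, dt, 5), tolerance = 1e-12)
  }
  # tiles overlapping the recording edges are clipped
  expect_equal(bnncode:::tileLength(c(0.005, 4.999), 0.01, 5),
               0.015 + 0.011, tolerance = 1e-12)
})

test_that("independent Poisson trains average an STTC of zero", {
  set.seed(22)
  vals <- vapply(1:200, function(r) {
    a <- sort(runif(rpois(1, 2 * 600), 0, 600))
    b <- sort(runif(rpois(1, 2 * 600), 0, 600))
    sttc(a, b, 600)
  }, numeric(1))
  expect_lt(abs(mean(vals)), 0.02)
})

test_that("representative-channel selection is spatial and deterministic", {
  grid <- as.matrix(expand.grid(x = 1:32, y = 1:32))
  ids <- selectRepresentativeChannels(grid, k = 40, seed = 30)
  expect_length(ids, 40)
  expect_length(unique(ids), 40)
  expect_true(all(ids >= 0 & ids < 1024))
  # spatially spread: selected points cover most of the grid extent
  sel <- grid[ids + 1, ]
  expect_gt(diff(range(sel[, 1])), 24)
  expect_gt(diff(range(sel[, 2])), 24)
  expect_identical(ids, selectRepresentativeChannels(grid, 40, seed = 30))

  expect_identical(selectRepresentativeChannels(grid[1:10, ], k = 10),
                   0:9)
  expect_error(selectRepresentativeChannels(grid[1:5, ], k = 10), "fewer")
})

test_that("edge significance is calibrated on independent trains", {
  set.seed(31)
  trains <- lapply(1:12, function(i) sort(runif(rpois(1, 120), 0, 60)))
  g <- buildConnectivityGraph(trains, 60, nSurrogates = 100, seed = 32)
  A <- adjacency(g)
  expect_true(all(A == t(A)))
  expect_true(all(diag(A) == 0))
  nPairs <- choose(12, 2)
  density <- sum(A[upper.tri(A)]) / nPairs
  expect_lte(density, 0.05 + 2 * sqrt(0.05 / nPairs))
})

test_that("a synchronous pair is always detected", {
  for (s in 1:20) {
    set.seed(40 + s)
    base <- sort(runif(120, 0, 60))
    trains <- c(list(base, base + rnorm(120, 0, 0.001)),
                lapply(1:4, function(i) sort(runif(120, 0, 60))))
    trains <- lapply(trains, function(t) sort(pmin(pmax(t, 0), 60)))
    g <- buildConnectivityGraph(trains, 60, nSurrogates = 50,
                                seed = 50 + s)
    expect_equal(adjacency(g)[1, 2], 1)
  }
})

test_that("degree and strength satisfy their defining sums", {
  # star: center + 5 leaves, all weights 0.5
  A <- matrix(0, 6, 6); A[1, 2:6] <- 1; A[2:6, 1] <- 1
  g <- new("ConnectivityGraph", nodes = 0:5, coords = cbind(1:6, 0),
           adjacency = A, weights = A * 0.5, partition = integer(0))
  m <- nodeMetrics(g)
  expect_equal(m$degree[1], 5L)
  expect_equal(m$strength[1], 2.5)
  expect_equal(m$degree[-1], rep(1L, 5))

  emptyG <- new("ConnectivityGraph", nodes = 0:3, coords = cbind(1:4, 0),
                adjacency = matrix(0, 4, 4), weights = matrix(0, 4, 4),
                partition = integer(0))
  expect_true(all(nodeMetrics(emptyG)$degree == 0))
  expect_true(all(nodeMetrics(emptyG)$strength == 0))

  set.seed(33)
  B <- matrix(rbinom(100, 1, 0.3), 10, 10)
  B <- 1 * ((B + t(B)) > 0); diag(B) <- 0
  rg <- new("ConnectivityGraph", nodes = 0:9, coords = cbind(1:10, 0),
            adjacency = B, weights = B * 0.1, partition = integer(0))
  expect_equal(sum(nodeMetrics(rg)$degree), 2 * sum(B[upper.tri(B)]))
})

test_that("consensus clustering recovers planted modules", {
  g <- cliqueGraph(c(5, 5))
  part <- modulePartition(consensusModules(g, nRuns = 25, seed = 60))
  expect_length(part, 10)
  expect_length(unique(part), 2)
  expect_length(unique(part[1:5]), 1)
  expect_length(unique(part[6:10]), 1)

  # assortative 4-block stochastic block model
  set.seed(61)
  sizes <- rep(8, 4)
  n <- sum(sizes)
  planted <- rep(1:4, times = sizes)
  P <- matrix(0.05, n, n)
  P[outer(planted, planted, "==")] <- 0.85
  A <- matrix(0, n, n)
  up <- upper.tri(A)
  A[up] <- rbinom(sum(up), 1, P[up])
  A <- A + t(A)
  sg <- new("ConnectivityGraph", nodes = seq_len(n) - 1L,
            coords = cbind(seq_len(n), 0), adjacency = A,
            weights = A * 0.3, partition = integer(0))
  found <- modulePartition(consensusModules(sg, nRuns = 50, seed = 62))
  expect_gte(adjustedRand(found, planted), 0.9)
})

test_that("within-module z-scores standardize each module", {
  # star of 4 leaves: center degree 4 = mean + 2 sd within the module
  A <- matrix(0, 5, 5); A[1, 2:5] <- 1; A[2:5, 1] <- 1
  g <- new("ConnectivityGraph", nodes = 0:4, coords = cbind(1:5, 0),
           adjacency = A, weights = A * 0.5,
           partition = rep(1L, 5))
  z <- withinModuleZ(g)
  expect_equal(z[1], 2)

  cg <- cliqueGraph(c(4, 6))
  zc <- withinModuleZ(cg, partition = rep(1:2, c(4, 6)))
  expect_true(all(zc == 0))            # equal within-degrees

  set.seed(63)
  B <- matrix(rbinom(400, 1, 0.4), 20, 20)
  B <- 1 * ((B + t(B)) > 0); diag(B) <- 0
  rg <- new("ConnectivityGraph", nodes = 0:19, coords = cbind(1:20, 0),
            adjacency = B, weights = B * 0.2, partition = integer(0))
  part <- rep(1:2, each = 10)
  zr <- withinModuleZ(rg, part)
  for (m in 1:2) expect_lt(abs(mean(zr[part == m])), 1e-12)
})

test_that("participation coefficients respect their bounds and examples", {
  cg <- cliqueGraph(c(5, 5))
  p0 <- participationCoeff(cg, rep(1:2, each = 5))
  expect_true(all(p0 == 0))            # all edges within own module

  # degree-4 node spread evenly over 4 modules
  A <- matrix(0, 5, 5); A[1, 2:5] <- 1; A[2:5, 1] <- 1
  g <- new("ConnectivityGraph", nodes = 0:4, coords = cbind(1:5, 0),
           adjacency = A, weights = A * 0.1,
           partition = c(1L, 1L, 2L, 3L, 4L))
  expect_equal(participationCoeff(g)[1], 0.75)

  set.seed(64)
  B <- matrix(rbinom(225, 1, 0.4), 15, 15)
  B <- 1 * ((B + t(B)) > 0); diag(B) <- 0
  rg <- new("ConnectivityGraph", nodes = 0:14, coords = cbind(1:15, 0),
            adjacency = B, weights = B * 0.2, partition = integer(0))
  part <- sample(1:3, 15, replace = TRUE)
  pr <- participationCoeff(rg, part)
  expect_true(all(pr >= 0))
  expect_true(all(pr <= 1 - 1 / length(unique(part)) + 1e-12))
})

test_that("condition comparison reports Welch statistics per metric", {
  g <- cliqueGraph(c(4, 4))
  cmp <- compareConditions(g, g)
  expect_true(all(c("metric", "nBefore", "meanBefore", "sdBefore",
                    "nAfter", "meanAfter", "sdAfter", "t", "p") %in%
                    names(cmp)))
  expect_true(all(cmp$p >= 0.99))
  expect_true(all(abs(cmp$t) < 1e-8))
})
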