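# total length of the union of the tiles [t - dt, t + dt], clipped to
# [0, recordingLength]; t must be sorted ascending
tileLength <- function(t, dt, recordingLength) {
  if (!length(t)) return(0)
  s <- pmax(t - dt, 0)
  e <- pmin(t + dt, recordingLength)
  ce <- cummax(e)
  begin <- c(TRUE, s[-1L] > ce[-length(ce)])
  gs <- s[begin]
  ge <- ce[c(which(begin)[-1L] - 1L, length(ce))]
  sum(ge - gs)
}

# fraction of spikes in a that lie within +/- dt of some spike in b
propWithin <- function(a, b, dt) {
  if (!length(a) || !length(b)) return(0)
  j <- findInterval(a, b)
  dLeft <- ifelse(j >= 1L, a - b[pmax(j, 1L)], Inf)
  dRight <- ifelse(j < length(b), b[pmin(j + 1L, length(b))] - a, Inf)
  mean(pmin(dLeft, dRight) <= dt + 1e-12)
}

#' Spike time tiling coefficient between two spike trains
#'
#' A firing-rate-insensitive correlation in \[-1, 1\]:
#' `STTC = 0.5 * ((P_A - T_B)/(1 - P_A T_B) + (P_B - T_A)/(1 - P_B T_A))`
#' where `T_A` is the fraction of the recording covered by the union of
#' tiles of width +/- dt around A's spikes (clipped at the recording
#' edges) and `P_A` the fraction of A's spikes within +/- dt of a spike of
#' B. An empty train yields 0 with a warning; near-singular denominators
#' are clamped at 1e-12.
#'
#' @param a,b sorted spike-time vectors (seconds) on a common recording.
#' @param recordingLength common recording length T, seconds.
#' @param dt coincidence half-window, seconds (default 0.010).
#' @return STTC value in \[-1, 1\].
#' @examples
#' t <- c(0.5, 1.2, 3.4)
#' sttc(t, t, recordingLength = 10)  # identical trains: 1
#' @export
sttc <- function(a, b, recordingLength, dt = 0.010) {
  recordingLength <- assertNumber(recordingLength, "recordingLength",
                                  lower = 1e-12)
  dt <- assertNumber(dt, "dt", lower = 1e-12)
  a <- sort(as.numeric(a)); b <- sort(as.numeric(b))
  if (!length(a) || !length(b)) {
    warning("empty spike train: STTC defined as 0")
    return(0)
  }
  tA <- tileLength(a, dt, recordingLength) / recordingLength
  tB <- tileLength(b, dt, recordingLength) / recordingLength
  pA <- propWithin(a, b, dt)
  pB <- propWithin(b, a, dt)
  d1 <- 1 - pA * tB
  d2 <- 1 - pB * tA
  d1 <- sign(d1 + (d1 == 0)) * max(abs(d1), 1e-12)
  d2 <- sign(d2 + (d2 == 0)) * max(abs(d2), 1e-12)
  val <- 0.5 * ((pA - tB) / d1 + (pB - tA) / d2)
  min(max(val, -1), 1)
}

#' Select spatially representative channels by K-means
#'
#' Clusters the channel coordinates into k groups (10 restarts, fixed
#' seed) and returns the single channel nearest each final centroid;
#' duplicate nearest channels are resolved by the next-nearest rule so the
#' result has exactly k unique ids.
#'
#' @param positions n x 2 matrix of channel coordinates (row i is channel
#'   id i - 1).
#' @param k number of representative channels (default 40).
#' @param seed integer seed.
#' @return integer vector of k unique 0-based channel ids (ascending).
#' @export
selectRepresentativeChannels <- function(positions, k = 40L, seed = 1L) {
  positions <- as.matrix(positions)
  k <- assertCount(k, "k", lower = 1L)
  n <- nrow(positions)
  if (n < k)
    stop("fewer channels than representatives requested", call. = FALSE)
  if (n == k) return(seq_len(n) - 1L)
  set.seed(tagSeed(seed, "kmeans-channels"))
  # highly symmetric layouts (regular electrode grids) can keep
  # Hartigan-Wong oscillating; approximate centroids are fine here, so
  # the non-convergence warning is muffled
  km <- withCallingHandlers(
    kmeans(positions, centers = k, nstart = 10L, iter.max = 500L),
    warning = function(w) {
      if (grepl("did not converge", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  chosen <- integer(0)
  for (cc in seq_len(k)) {
    d2 <- colSums((t(positions) - km$centers[cc, ])^2)
    for (cand in order(d2)) {
      if (!(cand %in% chosen)) { chosen <- c(chosen, cand); break }
    }
  }
  sort(chosen) - 1L
}

#' Build the significant-edge functional-connectivity graph
#'
#' Computes pairwise STTC between the representative trains, then keeps
#' edge (i, j) iff its observed STTC exceeds the (1 - alpha) quantile of
#' STTC values from spike-time-jittered surrogates (each surrogate run
#' jitters every spike independently by a uniform offset, clipped to the
#' recording). Kept edges carry the observed STTC as weight.
#'
#' @param trains list of sorted spike-time vectors (one per node).
#' @param recordingLength recording length, seconds.
#' @param dt STTC coincidence half-window, seconds.
#' @param nSurrogates number of jitter surrogates.
#' @param alpha one-sided significance level.
#' @param jitter half-width of the uniform jitter, seconds.
#' @param seed integer seed.
#' @param coords optional n x 2 node coordinates (defaults to a line).
#' @param nodeIds optional 0-based channel ids (defaults to 0:(n-1)).
#' @return a [ConnectivityGraph-class].
#' @export
buildConnectivityGraph <- function(trains, recordingLength, dt = 0.010,
                                   nSurrogates = 100L, alpha = 0.05,
                                   jitter = 0.050, seed = 1L,
                                   coords = NULL, nodeIds = NULL) {
  stopifnot(is.list(trains), length(trains) >= 2L)
  n <- length(trains)
  nSurrogates <- assertCount(nSurrogates, "nSurrogates", lower = 1L)
  alpha <- assertNumber(alpha, "alpha", lower = 1e-6, upper = 0.5)
  coords <- if (is.null(coords)) cbind(seq_len(n) - 1, 0) else
    as.matrix(coords)
  nodeIds <- if (is.null(nodeIds)) seq_len(n) - 1L else
    as.integer(nodeIds)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)

  obs <- matrix(0, n, n)
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1L]; j <- pairs[r, 2L]
    v <- suppressWarnings(sttc(trains[[i]], trains[[j]],
                               recordingLength, dt))
    obs[i, j] <- obs[j, i] <- v
  }
  set.seed(tagSeed(seed, "jitter-surrogates"))
  null <- array(0, c(nrow(pairs), nSurrogates))
  for (s in seq_len(nSurrogates)) {
    jt <- lapply(trains, function(t) {
      if (!length(t)) return(t)
      sort(pmin(pmax(t + runif(length(t), -jitter, jitter), 0),
                recordingLength))
    })
    for (r in seq_len(nrow(pairs)))
      null[r, s] <- suppressWarnings(
        sttc(jt[[pairs[r, 1L]]], jt[[pairs[r, 2L]]], recordingLength, dt))
  }
  A <- matrix(0, n, n)
  W <- matrix(0, n, n)
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1L]; j <- pairs[r, 2L]
    thr <- quantile(null[r, ], probs = 1 - alpha, names = FALSE,
                    type = 7)
    if (obs[i, j] > thr) {
      A[i, j] <- A[j, i] <- 1
      W[i, j] <- W[j, i] <- obs[i, j]
    }
  }
  new("ConnectivityGraph", nodes = nodeIds, coords = coords,
      adjacency = A, weights = W, partition = integer(0))
}

#' Node degree, strength and (when partitioned) hub metrics
#'
#' Degree `K_i = sum_j A_ij`, strength `S_i = sum_j w_ij` over incident
#' significant edges; if the graph carries a module partition, the
#' within-module degree z-score and participation coefficient are
#' appended.
#'
#' @param g a [ConnectivityGraph-class].
#' @return data.frame with one row per node: `node`, `degree`, `strength`
#'   (and `z`, `participation` when partitioned).
#' @export
nodeMetrics <- function(g) {
  stopifnot(is(g, "ConnectivityGraph"))
  validObject(g)
  out <- data.frame(node = g@nodes,
                    degree = as.integer(rowSums(g@adjacency)),
                    strength = rowSums(g@weights))
  if (length(g@partition)) {
    out$z <- withinModuleZ(g, g@partition)
    out$participation <- participationCoeff(g, g@partition)
  }
  out
}

#' Consensus module partition by repeated Louvain clustering
#'
#' Runs weighted Louvain community detection `nRuns` times under random
#' node orderings, builds the co-assignment consensus matrix, thresholds
#' it at 0.5 and reclusters, iterating (at most 10 rounds) until all runs
#' agree. Deterministic given `seed`. Negative edge weights are clipped at
#' 0 for the clustering.
#'
#' @param g a [ConnectivityGraph-class].
#' @param nRuns Louvain runs per consensus round.
#' @param seed integer seed.
#' @return the graph with its `partition` slot set (integer module ids).
#' @export
consensusModules <- function(g, nRuns = 100L, seed = 1L) {
  stopifnot(is(g, "ConnectivityGraph"))
  nRuns <- assertCount(nRuns, "nRuns", lower = 1L)
  set.seed(tagSeed(seed, "consensus"))
  n <- length(g@nodes)
  louvainOnce <- function(W) {
    perm <- sample.int(n)
    ig <- igraph::graph_from_adjacency_matrix(
      pmax(W[perm, perm], 0), mode = "undirected", weighted = TRUE,
      diag = FALSE)
    mem <- igraph::membership(igraph::cluster_louvain(ig))
    out <- integer(n)
    out[perm] <- as.integer(mem)
    out
  }
  W <- g@weights
  if (all(W[g@adjacency == 1] == 0)) W <- g@adjacency
  for (round in seq_len(10L)) {
    runs <- replicate(nRuns, louvainOnce(W))
    first <- runs[, 1L]
    same <- vapply(seq_len(nRuns), function(r)
      all(outer(runs[, r], runs[, r], "==") ==
            outer(first, first, "==")), logical(1))
    if (all(same)) {
      g@partition <- as.integer(factor(first))
      validObject(g)
      return(g)
    }
    D <- matrix(0, n, n)
    for (r in seq_len(nRuns))
      D <- D + outer(runs[, r], runs[, r], "==")
    D <- D / nRuns
    diag(D) <- 0
    W <- (D >= 0.5) * D
  }
  g@partition <- as.integer(factor(runs[, 1L]))
  validObject(g)
  g
}

#' Within-module degree z-score
#'
#' `z_i = (k_i - mean(k, module)) / sd(k, module)` with `k_i` the number
#' of edges from node i to nodes of its own module and the sd taken over
#' the module's nodes (population form); nodes in singleton modules or
#' modules with zero degree spread get z = 0.
#'
#' @param g a [ConnectivityGraph-class].
#' @param partition integer module id per node (defaults to the graph's
#'   stored partition).
#' @return numeric vector of z-scores, one per node.
#' @export
withinModuleZ <- function(g, partition = modulePartition(g)) {
  stopifnot(is(g, "ConnectivityGraph"))
  if (!length(partition)) stop("graph has no module partition",
                               call. = FALSE)
  A <- g@adjacency
  n <- nrow(A)
  z <- numeric(n)
  for (m in unique(partition)) {
    mem <- which(partition == m)
    kin <- rowSums(A[mem, mem, drop = FALSE])
    s <- sqrt(mean((kin - mean(kin))^2))
    if (length(mem) < 2L || is.na(s) || s == 0) next
    z[mem] <- (kin - mean(kin)) / s
  }
  z
}

#' Participation coefficient
#'
#' `P_i = 1 - sum_s (K_is / K_i)^2` over modules s, with `K_is` the number
#' of edges from node i into module s; isolated nodes get 0. Close to 1
#' when a node's edges spread evenly over all modules, 0 when they stay in
#' its own module.
#'
#' @inheritParams withinModuleZ
#' @return numeric vector in \[0, 1), one value per node.
#' @export
participationCoeff <- function(g, partition = modulePartition(g)) {
  stopifnot(is(g, "ConnectivityGraph"))
  if (!length(partition)) stop("graph has no module partition",
                               call. = FALSE)
  A <- g@adjacency
  K <- rowSums(A)
  p <- numeric(nrow(A))
  mods <- unique(partition)
  for (i in seq_len(nrow(A))) {
    if (K[i] == 0) next
    ks <- vapply(mods, function(m) sum(A[i, partition == m]), numeric(1))
    p[i] <- 1 - sum((ks / K[i])^2)
  }
  p
}

#' Compare network metrics between two conditions
#'
#' Welch two-sample t-tests on each node/edge metric of two connectivity
#' graphs (e.g. before vs after training): degree, strength, kept-edge
#' weight, and, when both graphs are partitioned, within-module z and
#' participation coefficient. Identical degenerate samples report t = 0,
#' p = 1.
#'
#' @param before,after [ConnectivityGraph-class] objects (run
#'   [consensusModules()] first to include the module metrics).
#' @return data.frame with one row per metric: sample sizes, mean, sd per
#'   condition, Welch `t`, `df` and `p`.
#' @export
compareConditions <- function(before, after) {
  mb <- nodeMetrics(before)
  ma <- nodeMetrics(after)
  pull <- function(g) g@weights[upper.tri(g@weights) & g@adjacency == 1]
  sets <- list(degree = list(mb$degree, ma$degree),
               strength = list(mb$strength, ma$strength),
               edgeWeight = list(pull(before), pull(after)))
  if (!is.null(mb$z) && !is.null(ma$z)) {
    sets$z <- list(mb$z, ma$z)
    sets$participation <- list(mb$participation, ma$participation)
  }
  rows <- lapply(names(sets), function(nm) {
    x <- sets[[nm]][[1]]; y <- sets[[nm]][[2]]
    tt <- tryCatch(t.test(x, y, var.equal = FALSE),
                   error = function(e) NULL)
    data.frame(metric = nm, nBefore = length(x), meanBefore = mean(x),
               sdBefore = sd(x), nAfter = length(y), meanAfter = mean(y),
               sdAfter = sd(y),
               t = if (is.null(tt)) 0 else unname(tt$statistic),
               df = if (is.null(tt)) NA_real_ else
                 unname(tt$parameter),
               p = if (is.null(tt)) 1 else tt$p.value)
  })
  do.call(rbind, rows)
}
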