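#' FeatureMapSet: eight normalized 5x5 feature maps
#'
#' Container for the output of the convolutional feature extractor: eight
#' 5x5 maps, min-max normalized to \[0, 1\]. Each map is the receptive field
#' feeding one of the eight stimulation electrodes.
#'
#' @slot maps numeric array of dimension 5 x 5 x 8, values in \[0, 1\].
#' @slot imageId character scalar identifying the source image (may be "").
#' @exportClass FeatureMapSet
setClass("FeatureMapSet",
  representation(maps = "array", imageId = "character"),
  prototype(maps = array(0, c(5, 5, 8)), imageId = ""))

setValidity("FeatureMapSet", function(object) {
  m <- object@maps
  if (length(dim(m)) != 3L || !all(dim(m) == c(5L, 5L, 8L)))
    return("'maps' must be a 5 x 5 x 8 array")
  if (!all(is.finite(m))) return("'maps' must be finite")
  if (min(m) < 0 || max(m) > 1) return("'maps' values must lie in [0, 1]")
  if (length(object@imageId) != 1L) return("'imageId' must be length 1")
  TRUE
})

#' PulseProgram: an 8-channel biphasic pulse stimulation program
#'
#' One encoded stimulus: per-channel pulse onset times on the oscillation
#' peak grid, plus the biphasic pulse shape metadata (amplitude, phase
#' duration) and provenance.
#'
#' @slot channels list of 8 ascending numeric vectors of onset times
#'   (seconds) within \[0, window).
#' @slot window stimulation duration in seconds (default 2).
#' @slot slotPeriod oscillation period in seconds (peak spacing; default 0.2).
#' @slot pulseAmplitude pulse amplitude in mV.
#' @slot phaseDuration duration of each biphasic phase in microseconds.
#' @slot provenance list with source image id and config hash.
#' @exportClass PulseProgram
setClass("PulseProgram",
  representation(channels = "list", window = "numeric",
                 slotPeriod = "numeric", pulseAmplitude = "numeric",
                 phaseDuration = "numeric", provenance = "list"),
  prototype(channels = rep(list(numeric(0)), 8L), window = 2,
            slotPeriod = 0.2, pulseAmplitude = 500, phaseDuration = 500,
            provenance = list()))

setValidity("PulseProgram", function(object) {
  ch <- object@channels
  if (length(ch) != 8L) return("a pulse program has exactly 8 channels")
  Tw <- object@window
  Ts <- object@slotPeriod
  if (Ts <= 0 || Tw <= 0) return("window and slotPeriod must be positive")
  for (k in seq_along(ch)) {
    t <- ch[[k]]
    if (length(t) == 0L) next
    if (is.unsorted(t, strictly = TRUE))
      return(sprintf("channel %d times must be strictly ascending", k))
    if (min(t) < 0 || max(t) >= Tw)
      return(sprintf("channel %d times must lie in [0, window)", k))
    off <- abs(t / Ts - round(t / Ts))
    if (max(off) > 1e-9)
      return(sprintf("channel %d has a pulse off the peak grid", k))
    if (length(t) > 1L && min(diff(t)) < Ts - 1e-9)
      return(sprintf("channel %d violates the minimum inter-pulse interval",
                     k))
  }
  TRUE
})

#' PulseMatrix: binary slot-grid view of a pulse program
#'
#' An 8 x 10 binary matrix U: rows are stimulation channels, columns the
#' ten 200 ms oscillation-peak slots of the 2 s window; U\[c, k\] = 1 iff
#' channel c fires a pulse in slot k.
#'
#' @slot bits integer matrix of 0/1, 8 rows x 10 columns by default.
#' @slot slotPeriod slot spacing in seconds.
#' @exportClass PulseMatrix
setClass("PulseMatrix",
  representation(bits = "matrix", slotPeriod = "numeric"),
  prototype(bits = matrix(0L, 8L, 10L), slotPeriod = 0.2))

setValidity("PulseMatrix", function(object) {
  b <- object@bits
  if (!all(b %in% c(0L, 1L))) return("'bits' entries must be 0 or 1")
  if (object@slotPeriod <= 0) return("'slotPeriod' must be positive")
  TRUE
})

#' SpikeEventTable: (channel, time) spike events with recording metadata
#'
#' The universal recording object: a time-sorted table of spike events from
#' a multichannel extracellular recording (real or simulated).
#'
#' @slot events data.frame with integer column `channel` (0-based id) and
#'   numeric column `time` (seconds), sorted by time.
#' @slot nChannels number of recording channels.
#' @slot duration recording length in seconds.
#' @slot metadata list: stimulus id, trial index, stage, ... (free-form).
#' @exportClass SpikeEventTable
setClass("SpikeEventTable",
  representation(events = "data.frame", nChannels = "integer",
                 duration = "numeric", metadata = "list"),
  prototype(events = data.frame(channel = integer(0), time = numeric(0)),
            nChannels = 1024L, duration = 0, metadata = list()))

setValidity("SpikeEventTable", function(object) {
  ev <- object@events
  if (!all(c("channel", "time") %in% names(ev)))
    return("'events' needs columns 'channel' and 'time'")
  if (nrow(ev)) {
    if (is.unsorted(ev$time)) return("'events' must be sorted by time")
    if (min(ev$time) < 0 || max(ev$time) > object@duration)
      return("event times must lie in [0, duration]")
    if (min(ev$channel) < 0L || max(ev$channel) >= object@nChannels)
      return("channel ids must lie in [0, nChannels)")
  }
  if (object@nChannels < 1L) return("'nChannels' must be >= 1")
  if (object@duration < 0) return("'duration' must be >= 0")
  TRUE
})

#' TrainedDecoder: PCA basis plus multinomial logistic-regression fit
#'
#' The decoding model: per-feature centering and PCA rotation, and the
#' (k-1) x (d+1) coefficient matrix of a multinomial logit with the last
#' class as the reference pattern.
#'
#' @slot center numeric vector of per-feature means (length = raw features).
#' @slot rotation PCA loading matrix (raw features x kept components); a
#'   0-column matrix marks the degenerate zero-variance bypass.
#' @slot beta coefficient matrix, (k-1) rows x (d+1) columns
#'   (intercept first).
#' @slot classes character vector of the k class labels; the last one is
#'   the reference pattern.
#' @slot lossTrace numeric vector of the training loss at each iteration.
#' @slot converged logical: loss change fell below tolerance before the
#'   iteration cap.
#' @exportClass TrainedDecoder
setClass("TrainedDecoder",
  representation(center = "numeric", rotation = "matrix", beta = "matrix",
                 classes = "character", lossTrace = "numeric",
                 converged = "logical"))

setValidity("TrainedDecoder", function(object) {
  k <- length(object@classes)
  if (k < 2L) return("a decoder needs at least 2 classes")
  if (nrow(object@beta) != k - 1L)
    return("'beta' must have k-1 rows (reference class implicit)")
  if (ncol(object@beta) != ncol(object@rotation) + 1L)
    return("'beta' must have (pca dimension + 1) columns")
  TRUE
})

#' ConnectivityGraph: STTC-weighted functional-connectivity graph
#'
#' Undirected graph over representative channels: binary adjacency for
#' significant functional connections, STTC edge weights, node coordinates
#' and (optionally) a module partition.
#'
#' @slot nodes integer vector of representative channel ids (0-based).
#' @slot coords numeric matrix (n x 2) of node spatial coordinates.
#' @slot adjacency symmetric 0/1 matrix, zero diagonal.
#' @slot weights symmetric numeric matrix of STTC weights on kept edges
#'   (0 where adjacency is 0); values in \[-1, 1\].
#' @slot partition integer module id per node (empty until
#'   [consensusModules()] is run).
#' @exportClass ConnectivityGraph
setClass("ConnectivityGraph",
  representation(nodes = "integer", coords = "matrix",
                 adjacency = "matrix", weights = "matrix",
                 partition = "integer"),
  prototype(partition = integer(0)))

setValidity("ConnectivityGraph", function(object) {
  n <- length(object@nodes)
  A <- object@adjacency
  W <- object@weights
  if (!all(dim(A) == c(n, n))) return("'adjacency' must be n x n")
  if (!all(dim(W) == c(n, n))) return("'weights' must be n x n")
  if (!all(A %in% c(0, 1))) return("'adjacency' entries must be 0/1")
  if (any(A != t(A))) return("'adjacency' must be symmetric")
  if (max(abs(W - t(W))) > 1e-12) return("'weights' must be symmetric")
  if (any(diag(A) != 0)) return("no self-loops allowed")
  if (nrow(W) && (min(W) < -1 - 1e-12 || max(W) > 1 + 1e-12))
    return("STTC weights must lie in [-1, 1]")
  if (any(W[A == 0] != 0)) return("weights only on kept edges")
  if (length(object@partition) && length(object@partition) != n)
    return("'partition' must assign one module per node")
  TRUE
})
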