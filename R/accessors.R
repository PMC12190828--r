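#' @name accessors
#' @title Accessors for bnncode S4 objects
#' @description Accessor generics for the core data classes: prefer these
#'   over direct slot access.
#' @param x an object of the documented class.
#' @return The slot value (see the individual accessor).
NULL

#' @describeIn accessors the 5 x 5 x 8 array of normalized feature maps.
#' @export
setGeneric("featureMaps", function(x) standardGeneric("featureMaps"))
setMethod("featureMaps", "FeatureMapSet", function(x) x@maps)

#' @describeIn accessors list of 8 per-channel pulse onset-time vectors.
#' @export
setGeneric("pulseTimes", function(x) standardGeneric("pulseTimes"))
setMethod("pulseTimes", "PulseProgram", function(x) x@channels)

#' @describeIn accessors the spike event data.frame (channel, time).
#' @export
setGeneric("spikeEvents", function(x) standardGeneric("spikeEvents"))
setMethod("spikeEvents", "SpikeEventTable", function(x) x@events)

#' @describeIn accessors number of recording channels.
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))
setMethod("nChannels", "SpikeEventTable", function(x) x@nChannels)

#' @describeIn accessors recording duration in seconds.
#' @export
setGeneric("recordingDuration",
           function(x) standardGeneric("recordingDuration"))
setMethod("recordingDuration", "SpikeEventTable", function(x) x@duration)

#' @describeIn accessors free-form recording metadata list.
#' @export
setGeneric("recordingMetadata",
           function(x) standardGeneric("recordingMetadata"))
setMethod("recordingMetadata", "SpikeEventTable", function(x) x@metadata)

#' @describeIn accessors binary slot matrix of a PulseMatrix.
#' @export
setGeneric("pulseBits", function(x) standardGeneric("pulseBits"))
setMethod("pulseBits", "PulseMatrix", function(x) x@bits)

#' @describeIn accessors binary adjacency matrix of a graph.
#' @export
setGeneric("adjacency", function(x) standardGeneric("adjacency"))
setMethod("adjacency", "ConnectivityGraph", function(x) x@adjacency)

#' @describeIn accessors STTC edge-weight matrix of a graph.
#' @export
setGeneric("edgeWeights", function(x) standardGeneric("edgeWeights"))
setMethod("edgeWeights", "ConnectivityGraph", function(x) x@weights)

#' @describeIn accessors module partition of a graph (integer per node).
#' @export
setGeneric("modulePartition",
           function(x) standardGeneric("modulePartition"))
setMethod("modulePartition", "ConnectivityGraph", function(x) x@partition)

#' @describeIn accessors representative channel ids of a graph.
#' @export
setGeneric("graphNodes", function(x) standardGeneric("graphNodes"))
setMethod("graphNodes", "ConnectivityGraph", function(x) x@nodes)

setMethod("show", "FeatureMapSet", function(object) {
  cat("FeatureMapSet: 8 maps of 5 x 5",
      if (nzchar(object@imageId)) sprintf("(image '%s')", object@imageId)
      else "", "\n")
  cat(sprintf("  value range: [%.3f, %.3f]\n",
              min(object@maps), max(object@maps)))
})

setMethod("show", "PulseProgram", function(object) {
  np <- vapply(object@channels, length, integer(1))
  cat(sprintf("PulseProgram: 8 channels, %d pulses in a %.1f s window\n",
              sum(np), object@window))
  cat(sprintf("  per-channel pulses: %s\n", paste(np, collapse = " ")))
  cat(sprintf("  biphasic pulse: %.0f mV, %.0f us/phase; slot %.0f ms\n",
              object@pulseAmplitude, object@phaseDuration,
              1000 * object@slotPeriod))
})

setMethod("show", "PulseMatrix", function(object) {
  cat(sprintf("PulseMatrix: %d x %d binary, %d pulses\n",
              nrow(object@bits), ncol(object@bits), sum(object@bits)))
})

setMethod("show", "SpikeEventTable", function(object) {
  cat(sprintf(
    "SpikeEventTable: %d events, %d channels, %.2f s\n",
    nrow(object@events), object@nChannels, object@duration))
  md <- object@metadata
  if (length(md))
    cat("  metadata:", paste(names(md), unlist(lapply(md, format)),
                             sep = "=", collapse = ", "), "\n")
})

setMethod("show", "TrainedDecoder", function(object) {
  cat(sprintf(
    "TrainedDecoder: %d classes (reference '%s'), %d PCA components\n",
    length(object@classes), tail(object@classes, 1L),
    ncol(object@rotation)))
  cat(sprintf("  final loss %.6g after %d iterations (%s)\n",
              tail(object@lossTrace, 1L), length(object@lossTrace),
              if (object@converged) "converged" else "iteration cap"))
})

setMethod("show", "ConnectivityGraph", function(object) {
  n <- length(object@nodes)
  ne <- sum(object@adjacency) / 2
  cat(sprintf("ConnectivityGraph: %d nodes, %d significant edges\n", n, ne))
  if (length(object@partition))
    cat(sprintf("  %d modules\n", length(unique(object@partition))))
})
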