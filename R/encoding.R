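#' Delayed-phase encoding configuration
#'
#' Parameters of the image-to-pulse transform. The spike-timing function
#' maps a normalized pixel value p to a latency
#' `t = tMax * (1 - atan(delta * p))` (stronger features fire earlier); a
#' row-major positional delay `i / nRf` seconds spreads the 25 pixels of a
#' receptive field over a 1 s span; times are snapped to the peaks of a
#' cosine subthreshold membrane oscillation `A cos(w t + phi0)` with period
#' `smoPeriod`, whose peaks define the 10 stimulation slots of the 2 s
#' window; duplicate aligned times are merged (compression). The defaults
#' jointly enforce a 2 s stimulation duration, a 200 ms minimum inter-pulse
#' interval and a 5 Hz maximum stimulation rate.
#'
#' @param tMax maximum pulse latency in seconds.
#' @param delta sharpness of the latency curve; the default `tan(1)` makes
#'   the latency hit exactly 0 at p = 1 (negative values from larger
#'   user-supplied `delta` are clamped to 0).
#' @param nRf pixels per receptive field (5 x 5 = 25).
#' @param delayScale span of the positional delay in seconds.
#' @param smoAmplitude,smoPhase0 cosine amplitude and initial phase
#'   (cosmetic: peak positions only depend on the period when phi0 = 0).
#' @param smoPeriod oscillation period T in seconds; peaks at k*T.
#' @param window stimulation duration in seconds.
#' @param minInterval minimum within-channel inter-pulse interval (s).
#' @param pulseAmplitude biphasic pulse amplitude, mV.
#' @param phaseDuration biphasic phase duration, microseconds.
#' @param significanceFloor minimum pixel value that emits a pulse; set to
#'   0 to make every pixel emit. Reproduces the class-dependent sparseness
#'   of encoded programs.
#' @return validated list of class `EncodingConfig`.
#' @export
encodingConfig <- function(tMax = 1, delta = tan(1), nRf = 25L,
                           delayScale = 1, smoAmplitude = 1,
                           smoPeriod = 0.2, smoPhase0 = 0, window = 2,
                           minInterval = 0.2, pulseAmplitude = 500,
                           phaseDuration = 500,
                           significanceFloor = 0.05) {
  cfg <- list(tMax = assertNumber(tMax, "tMax", lower = 1e-9),
              delta = assertNumber(delta, "delta", lower = 0),
              nRf = assertCount(nRf, "nRf", lower = 1L),
              delayScale = assertNumber(delayScale, "delayScale", lower = 0),
              smoAmplitude = assertNumber(smoAmplitude, "smoAmplitude"),
              smoPeriod = assertNumber(smoPeriod, "smoPeriod",
                                       lower = 1e-9),
              smoPhase0 = assertNumber(smoPhase0, "smoPhase0"),
              window = assertNumber(window, "window", lower = 1e-9),
              minInterval = assertNumber(minInterval, "minInterval",
                                         lower = 0),
              pulseAmplitude = assertNumber(pulseAmplitude,
                                            "pulseAmplitude"),
              phaseDuration = assertNumber(phaseDuration, "phaseDuration",
                                           lower = 0),
              significanceFloor = assertNumber(significanceFloor,
                                               "significanceFloor",
                                               lower = 0, upper = 1))
  if (cfg$smoPeriod < cfg$minInterval)
    stop("smoPeriod must be >= minInterval (peak slots enforce the ",
         "minimum interval)", call. = FALSE)
  slots <- cfg$window / cfg$smoPeriod
  if (abs(slots - round(slots)) > 1e-9)
    stop("window must be an integer multiple of smoPeriod", call. = FALSE)
  class(cfg) <- "EncodingConfig"
  cfg
}

#' Latency of a pixel: the spike-timing function
#'
#' `t = tMax * (1 - atan(delta * p))`, clamped below at 0. Strictly
#' decreasing in p: stronger features fire earlier.
#'
#' @param p normalized pixel value(s) in \[0, 1\].
#' @param cfg an [encodingConfig()].
#' @return latency in seconds, same length as `p`.
#' @examples
#' spikeTime(c(0, 1))      # tMax and 0
#' @export
spikeTime <- function(p, cfg = encodingConfig()) {
  stopifnot(inherits(cfg, "EncodingConfig"))
  if (!is.numeric(p) || any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("pixel values must lie in [0, 1]", call. = FALSE)
  pmax(cfg$tMax * (1 - atan(cfg$delta * p)), 0)
}

#' Positional delay of a pixel within its receptive field
#'
#' Pixel index i (0-based, row-major within the 5 x 5 map) is offset by
#' `(i / nRf) * delayScale` seconds, creating the temporal difference
#' between positions.
#'
#' @param i 0-based pixel index (vectorized), `0 <= i < nRf`.
#' @param cfg an [encodingConfig()].
#' @return delay in seconds.
#' @examples
#' positionDelay(c(0, 5, 24))
#' @export
positionDelay <- function(i, cfg = encodingConfig()) {
  stopifnot(inherits(cfg, "EncodingConfig"))
  if (!is.numeric(i) || any(i != round(i)) || any(i < 0) ||
      any(i >= cfg$nRf))
    stop(sprintf("pixel index must be an integer in [0, %d)", cfg$nRf),
         call. = FALSE)
  (i / cfg$nRf) * cfg$delayScale
}

#' Align a time to the nearest subthreshold-oscillation peak
#'
#' Peaks sit at `k * smoPeriod` for `k = 0 .. window/smoPeriod - 1` (the
#' window is half-open, so the last peak is `window - smoPeriod`). Ties are
#' broken toward the earlier peak; times beyond the last peak snap onto it.
#'
#' @param t time(s) in seconds within \[0, window\].
#' @param cfg an [encodingConfig()].
#' @return aligned time(s) on the peak grid.
#' @examples
#' smoAlign(c(0.29, 0.3))  # 0.2 both: nearest, tie to earlier
#' @export
smoAlign <- function(t, cfg = encodingConfig()) {
  stopifnot(inherits(cfg, "EncodingConfig"))
  if (!is.numeric(t) || any(!is.finite(t)) || any(t < 0) ||
      any(t > cfg$window))
    stop("time must lie within [0, window]", call. = FALSE)
  Tp <- cfg$smoPeriod
  kMax <- round(cfg$window / Tp) - 1
  ratio <- t / Tp
  k <- floor(ratio + 0.5)
  # half-way points must snap to the earlier peak; undo a round-up there
  tie <- abs(ratio %% 1 - 0.5) < 1e-9 & k > ratio
  k[tie] <- k[tie] - 1
  pmin(k, kMax) * Tp
}

#' Encode feature maps into an 8-channel pulse program
#'
#' For each of the 8 maps (one receptive field per stimulation electrode):
#' each pixel above the significance floor gets a raw time
#' `spikeTime(p_i) + positionDelay(i)`; raw times are snapped to the
#' oscillation peaks with [smoAlign()] and duplicate aligned times within a
#' channel are merged into a single pulse (compression).
#'
#' @param fm a [FeatureMapSet-class].
#' @param cfg an [encodingConfig()].
#' @return a [PulseProgram-class].
#' @export
encodePulses <- function(fm, cfg = encodingConfig()) {
  stopifnot(is(fm, "FeatureMapSet"), inherits(cfg, "EncodingConfig"))
  validObject(fm)
  maps <- featureMaps(fm)
  channels <- vector("list", 8L)
  for (ch in 1:8) {
    # row-major pixel order within the 5x5 map
    p <- as.vector(t(maps[, , ch]))
    keep <- p >= cfg$significanceFloor
    if (!any(keep)) {
      channels[[ch]] <- numeric(0)
      next
    }
    i <- which(keep) - 1L
    raw <- spikeTime(p[keep], cfg) + positionDelay(i, cfg)
    raw <- pmin(raw, cfg$window)
    channels[[ch]] <- sort(unique(smoAlign(raw, cfg)))
  }
  new("PulseProgram", channels = channels, window = cfg$window,
      slotPeriod = cfg$smoPeriod, pulseAmplitude = cfg$pulseAmplitude,
      phaseDuration = cfg$phaseDuration,
      provenance = list(imageId = fm@imageId, configHash = configHash(
        unclass(cfg))))
}

#' Binary slot-matrix view of a pulse program
#'
#' Maps the program onto an 8 x 10 binary matrix (channels x oscillation
#' peak slots): entry 1 marks a pulse at that channel and slot. The mapping
#' is invertible ([pulseProgramFromMatrix()]).
#'
#' @param pp a [PulseProgram-class].
#' @return a [PulseMatrix-class].
#' @export
pulseMatrix <- function(pp) {
  stopifnot(is(pp, "PulseProgram"))
  validObject(pp)
  nSlots <- as.integer(round(pp@window / pp@slotPeriod))
  bits <- matrix(0L, 8L, nSlots)
  for (ch in 1:8) {
    t <- pp@channels[[ch]]
    if (!length(t)) next
    k <- round(t / pp@slotPeriod)
    if (max(abs(t / pp@slotPeriod - k)) > 1e-9)
      stop("pulse off the slot grid", call. = FALSE)
    bits[ch, k + 1L] <- 1L
  }
  new("PulseMatrix", bits = bits, slotPeriod = pp@slotPeriod)
}

#' Rebuild a pulse program from its binary matrix view
#'
#' @param pm a [PulseMatrix-class].
#' @param pulseAmplitude,phaseDuration pulse shape metadata to attach.
#' @return a [PulseProgram-class] whose [pulseMatrix()] equals `pm`.
#' @export
pulseProgramFromMatrix <- function(pm, pulseAmplitude = 500,
                                   phaseDuration = 500) {
  stopifnot(is(pm, "PulseMatrix"))
  bits <- pulseBits(pm)
  channels <- lapply(seq_len(nrow(bits)), function(ch)
    (which(bits[ch, ] == 1L) - 1L) * pm@slotPeriod)
  new("PulseProgram", channels = channels,
      window = ncol(bits) * pm@slotPeriod, slotPeriod = pm@slotPeriod,
      pulseAmplitude = pulseAmplitude, phaseDuration = phaseDuration,
      provenance = list())
}

#' Euclidean distance between two binary pulse matrices
#'
#' `d = sqrt(sum_ij (U_ij - V_ij)^2)`: the dissimilarity of two encoded
#' stimulus programs. A metric on binary matrices of a common shape.
#'
#' @param U,V [PulseMatrix-class] objects (or bare matrices) of equal shape.
#' @return non-negative scalar; 0 iff identical.
#' @examples
#' u <- matrix(1, 8, 10); v <- matrix(0, 8, 10)
#' sequenceDistance(u, v)  # sqrt(80)
#' @export
sequenceDistance <- function(U, V) {
  u <- if (is(U, "PulseMatrix")) pulseBits(U) else U
  v <- if (is(V, "PulseMatrix")) pulseBits(V) else V
  if (!all(dim(u) == dim(v)))
    stop("matrices must have equal shape", call. = FALSE)
  sqrt(sum((u - v)^2))
}
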