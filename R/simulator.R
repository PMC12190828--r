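#' Simulator configuration for the synthetic in vitro network
#'
#' Phenomenological stand-in for a cultured network on a high-density
#' microelectrode array: per-channel Poisson background with network-wide
#' synchronized bursts, and stimulus-locked evoked transients whose
#' exponential kernel (tau = 50 ms) decays the firing rate back to baseline
#' well within 0.2 s of a pulse, matching the recovery seen in cultures.
#'
#' @param nChannels recording channels.
#' @param spontaneousRate baseline rate per channel, Hz.
#' @param burstRate network bursts per minute.
#' @param burstParticipation fraction of channels joining each burst.
#' @param burstExtra expected extra spikes per participating channel per
#'   burst.
#' @param burstWidth burst envelope width, seconds.
#' @param gain 8 x nChannels matrix: expected extra spikes per channel per
#'   pulse on each stimulation electrode (see [randomGainMatrix()]).
#' @param decayTau evoked-kernel time constant, seconds; with 0.05 the
#'   evoked rate at 0.2 s after a pulse is under 2% of its peak.
#' @param latency stimulus-to-response latency, seconds.
#' @param refractory per-channel refractory period, seconds (enforced on
#'   the background process and in spike detection).
#' @param plasticityDrift per-stage multiplier (> 1 amplifies) on the
#'   class-separable component of the gain matrix across training stages;
#'   1 disables drift.
#' @return validated list of class `SimulatorConfig`.
#' @export
simulatorConfig <- function(nChannels = 1024L, spontaneousRate = 0.5,
                            burstRate = 2, burstParticipation = 0.6,
                            burstExtra = 3, burstWidth = 0.1,
                            gain = NULL, decayTau = 0.05, latency = 0.002,
                            refractory = 0.002, plasticityDrift = 1) {
  nChannels <- assertCount(nChannels, "nChannels", lower = 1L)
  if (is.null(gain)) gain <- matrix(0, 8L, nChannels)
  if (!is.matrix(gain) || nrow(gain) != 8L || ncol(gain) != nChannels ||
      any(gain < 0))
    stop("'gain' must be a non-negative 8 x nChannels matrix",
         call. = FALSE)
  cfg <- list(nChannels = nChannels,
              spontaneousRate = assertNumber(spontaneousRate,
                                             "spontaneousRate", lower = 0),
              burstRate = assertNumber(burstRate, "burstRate", lower = 0),
              burstParticipation = assertNumber(burstParticipation,
                                                "burstParticipation",
                                                lower = 0, upper = 1),
              burstExtra = assertNumber(burstExtra, "burstExtra",
                                        lower = 0),
              burstWidth = assertNumber(burstWidth, "burstWidth",
                                        lower = 1e-6),
              gain = gain,
              decayTau = assertNumber(decayTau, "decayTau", lower = 1e-6),
              latency = assertNumber(latency, "latency", lower = 0),
              refractory = assertNumber(refractory, "refractory",
                                        lower = 0),
              plasticityDrift = assertNumber(plasticityDrift,
                                             "plasticityDrift",
                                             lower = 0))
  class(cfg) <- "SimulatorConfig"
  cfg
}

#' Random stimulation-gain matrix
#'
#' Draws the expected evoked spike count per (stimulation electrode,
#' recording channel) pair from a log-normal, giving each electrode a
#' distinct channel signature so that distinct pulse programs evoke
#' separable response patterns. A `sparsity` fraction of entries is zeroed
#' (most channels respond to few electrodes).
#'
#' @param nChannels recording channels.
#' @param meanGain mean expected extra spikes per pulse on responding
#'   entries.
#' @param sdlog log-scale sd of the log-normal.
#' @param sparsity fraction of (electrode, channel) pairs with zero gain.
#' @param seed integer seed.
#' @return 8 x nChannels non-negative matrix.
#' @export
randomGainMatrix <- function(nChannels, meanGain = 0.3, sdlog = 0.6,
                             sparsity = 0.6, seed = 1L) {
  nChannels <- assertCount(nChannels, "nChannels", lower = 1L)
  set.seed(tagSeed(seed, "gain-matrix"))
  g <- matrix(stats::rlnorm(8L * nChannels,
                            meanlog = log(meanGain) - sdlog^2 / 2,
                            sdlog = sdlog), 8L, nChannels)
  g[matrix(runif(8L * nChannels) < sparsity, 8L, nChannels)] <- 0
  g
}

enforceRefractory <- function(t, r) {
  if (length(t) < 2L || r <= 0) return(t)
  keep <- logical(length(t))
  last <- -Inf
  for (i in seq_along(t)) {
    if (t[i] - last >= r) {
      keep[i] <- TRUE
      last <- t[i]
    }
  }
  t[keep]
}

makeEventTable <- function(channel, time, nChannels, duration,
                           metadata = list()) {
  o <- order(time, channel)
  new("SpikeEventTable",
      events = data.frame(channel = as.integer(channel[o]),
                          time = as.numeric(time[o])),
      nChannels = as.integer(nChannels), duration = as.numeric(duration),
      metadata = metadata)
}

# Background process shared by the spontaneous and evoked paths: Poisson
# baseline plus network-wide bursts, refractory enforced per channel.
drawBackground <- function(duration, cfg) {
  ch <- integer(0); tm <- numeric(0)
  n <- rpois(cfg$nChannels, cfg$spontaneousRate * duration)
  if (sum(n) > 0) {
    ch <- rep.int(seq_len(cfg$nChannels) - 1L, n)
    tm <- runif(sum(n), 0, duration)
  }
  nB <- rpois(1L, cfg$burstRate / 60 * duration)
  if (nB > 0 && cfg$burstExtra > 0 && cfg$burstParticipation > 0) {
    tB <- runif(nB, 0, duration)
    for (b in seq_len(nB)) {
      part <- which(runif(cfg$nChannels) < cfg$burstParticipation) - 1L
      if (!length(part)) next
      nx <- rpois(length(part), cfg$burstExtra)
      if (sum(nx) == 0) next
      ch <- c(ch, rep.int(part, nx))
      tm <- c(tm, pmin(tB[b] + runif(sum(nx), 0, cfg$burstWidth),
                       duration))
    }
  }
  if (length(tm) && cfg$refractory > 0) {
    kept <- lapply(split(tm, ch), function(tt)
      enforceRefractory(sort(tt), cfg$refractory))
    ch <- rep.int(as.integer(names(kept)), lengths(kept))
    tm <- unlist(kept, use.names = FALSE)
  }
  list(channel = ch, time = tm)
}

#' Simulate spontaneous multichannel activity
#'
#' Homogeneous Poisson background per channel superposed with network-wide
#' synchronized bursts (a ~100 ms rate surge on a participating subset of
#' channels), refractory period enforced per channel. Deterministic given
#' `seed`.
#'
#' @param duration recording length, seconds.
#' @param cfg a [simulatorConfig()].
#' @param seed integer seed.
#' @param metadata metadata list attached to the recording.
#' @return a [SpikeEventTable-class].
#' @export
simulateSpontaneous <- function(duration, cfg = simulatorConfig(),
                                seed = 1L, metadata = list()) {
  stopifnot(inherits(cfg, "SimulatorConfig"))
  duration <- assertNumber(duration, "duration", lower = 1e-9)
  set.seed(tagSeed(seed, "spontaneous"))
  bg <- drawBackground(duration, cfg)
  makeEventTable(bg$channel, bg$time, cfg$nChannels, duration, metadata)
}

#' Simulate the evoked response to a pulse program
#'
#' Inhomogeneous Poisson superposition: on top of the spontaneous
#' background, every pulse at time tp on stimulation electrode e adds, on
#' channel c, an expected `gain[e, c]` spikes with density
#' `gain/tau * exp(-(t - tp - latency)/tau)` for `t > tp + latency`
#' (truncated at the window end). All evoked spikes respect causality.
#'
#' @param pp a [PulseProgram-class].
#' @param cfg a [simulatorConfig()].
#' @param seed integer seed.
#' @param gain optional gain-matrix override (8 x nChannels).
#' @param metadata metadata list attached to the recording.
#' @return a [SpikeEventTable-class] of duration `pp@window`.
#' @export
simulateEvoked <- function(pp, cfg = simulatorConfig(), seed = 1L,
                           gain = NULL, metadata = list()) {
  stopifnot(is(pp, "PulseProgram"), inherits(cfg, "SimulatorConfig"))
  validObject(pp)
  G <- gain %||% cfg$gain
  if (!is.matrix(G) || nrow(G) != 8L || ncol(G) != cfg$nChannels)
    stop("gain matrix must be 8 x nChannels", call. = FALSE)
  duration <- pp@window
  set.seed(tagSeed(seed, "evoked"))
  bg <- drawBackground(duration, cfg)
  ch <- bg$channel; tm <- bg$time
  for (e in 1:8) {
    for (tp in pp@channels[[e]]) {
      L <- duration - tp - cfg$latency
      if (L <= 0) next
      Fint <- 1 - exp(-L / cfg$decayTau)
      lam <- G[e, ] * Fint
      nx <- rpois(cfg$nChannels, lam)
      tot <- sum(nx)
      if (tot == 0) next
      u <- runif(tot)
      dt <- -cfg$decayTau * log(1 - u * Fint)
      ch <- c(ch, rep.int(seq_len(cfg$nChannels) - 1L, nx))
      tm <- c(tm, tp + cfg$latency + dt)
    }
  }
  makeEventTable(ch, tm, cfg$nChannels, duration, metadata)
}

#' Simulate a full staged stimulation session
#'
#' Delivers each of 9 pulse programs `repetitions` times (default 50) and
#' records `nSpontaneous` 2 s spontaneous segments, tagging every trial
#' with stimulus, trial index, training stage (trials 1-15, 16-30, 31-45)
#' and the post-stage test designation (the 5 trials after each stage
#' block: 16-20, 31-35, 46-50). The plasticity drift multiplies the
#' class-separable component of the gain matrix by
#' `plasticityDrift^(completed stages)` as the session progresses.
#'
#' @param programs list of 9 [PulseProgram-class] objects.
#' @param cfg a [simulatorConfig()].
#' @param seed integer seed.
#' @param repetitions stimulations per program.
#' @param nSpontaneous number of spontaneous segments.
#' @param spontaneousLen spontaneous segment length, seconds.
#' @param blank if TRUE, emit zero events everywhere (a chip without
#'   neurons; the chance-floor control).
#' @return list with elements `evoked` (list of SpikeEventTable, one per
#'   stimulus x trial) and `spontaneous` (list of SpikeEventTable).
#' @export
simulateSession <- function(programs, cfg = simulatorConfig(), seed = 1L,
                            repetitions = 50L, nSpontaneous = 50L,
                            spontaneousLen = 2, blank = FALSE) {
  if (length(programs) < 9L)
    stop("the staged protocol needs 9 pulse programs", call. = FALSE)
  stopifnot(inherits(cfg, "SimulatorConfig"))
  repetitions <- assertCount(repetitions, "repetitions", lower = 1L)
  nSpontaneous <- assertCount(nSpontaneous, "nSpontaneous", lower = 0L)
  blank <- assertFlag(blank, "blank")

  stageOf <- function(r) {
    if (r <= 15L) 1L else if (r <= 30L) 2L else if (r <= 45L) 3L else NA
  }
  testStageOf <- function(r) {
    if (r >= 16L && r <= 20L) 1L
    else if (r >= 31L && r <= 35L) 2L
    else if (r >= 46L && r <= 50L) 3L
    else NA
  }
  Gbar <- matrix(colMeans(cfg$gain), 8L, cfg$nChannels, byrow = TRUE)

  evoked <- vector("list", 9L * repetitions)
  idx <- 0L
  for (s in 1:9) {
    pp <- programs[[s]]
    for (r in seq_len(repetitions)) {
      idx <- idx + 1L
      md <- list(stimulus = s, trial = r, stage = stageOf(r),
                 testStage = testStageOf(r))
      if (blank) {
        evoked[[idx]] <- makeEventTable(integer(0), numeric(0),
                                        cfg$nChannels, pp@window, md)
        next
      }
      m <- cfg$plasticityDrift^(min((r - 1L) %/% 15L, 3L))
      Gs <- pmax(Gbar + m * (cfg$gain - Gbar), 0)
      evoked[[idx]] <- simulateEvoked(
        pp, cfg, seed = tagSeed(seed, sprintf("trial-%d-%d", s, r)),
        gain = Gs, metadata = md)
    }
  }
  spontaneous <- lapply(seq_len(nSpontaneous), function(r) {
    md <- list(stimulus = 0L, trial = r, stage = stageOf(r),
               testStage = testStageOf(r))
    if (blank)
      makeEventTable(integer(0), numeric(0), cfg$nChannels,
                     spontaneousLen, md)
    else
      simulateSpontaneous(spontaneousLen, cfg,
                          seed = tagSeed(seed, sprintf("spont-%d", r)),
                          metadata = md)
  })
  list(evoked = evoked, spontaneous = spontaneous)
}

#' Synthesize a raw voltage trace from spike events
#'
#' Gaussian background noise with a stereotyped biphasic spike waveform
#' added at each event time: the input fixture for the spike-detection
#' path.
#'
#' @param st a [SpikeEventTable-class].
#' @param fs sampling rate, Hz (> 6000).
#' @param noiseSd background noise standard deviation (signal units).
#' @param spikeAmplitude peak amplitude of the inserted waveform.
#' @param seed integer seed for the noise.
#' @return list of class `VoltageTrace`: `samples` (nChannels x nSamples
#'   matrix), `fs`, `eventCount`.
#' @export
synthesizeVoltage <- function(st, fs = 20000, noiseSd = 8,
                              spikeAmplitude = 96, seed = 1L) {
  stopifnot(is(st, "SpikeEventTable"))
  fs <- assertNumber(fs, "fs", lower = 6000 + 1e-9)
  nS <- max(1L, ceiling(st@duration * fs))
  set.seed(tagSeed(seed, "voltage"))
  v <- matrix(rnorm(st@nChannels * nS, 0, noiseSd), st@nChannels, nS)
  # biphasic template ~1.2 ms: sharp negative trough then positive rebound
  tt <- seq(0, 0.0012, by = 1 / fs)
  tpl <- -sin(2 * pi * tt / 0.0012) * exp(-tt / 0.0006)
  tpl <- tpl / max(abs(tpl)) * spikeAmplitude
  ev <- spikeEvents(st)
  for (i in seq_len(nrow(ev))) {
    s0 <- floor(ev$time[i] * fs) + 1L
    ixs <- s0:min(s0 + length(tpl) - 1L, nS)
    v[ev$channel[i] + 1L, ixs] <- v[ev$channel[i] + 1L, ixs] +
      tpl[seq_along(ixs)]
  }
  structure(list(samples = v, fs = fs, eventCount = nrow(ev)),
            class = "VoltageTrace")
}

#' Detect spikes in a raw voltage trace
#'
#' Band-passes each channel at 300-3000 Hz (4th-order zero-phase
#' Butterworth via forward-backward filtering), estimates the background
#' noise sd robustly as `median(|x|)/0.6745`, and marks a spike wherever
#' the filtered magnitude exceeds `thresholdK` times that sd; event time is
#' the extremum of each suprathreshold excursion, with a per-channel
#' refractory period between detections.
#'
#' @param v a `VoltageTrace` from [synthesizeVoltage()] (or a compatible
#'   list with `samples` and `fs`).
#' @param thresholdK detection threshold in robust noise sd units.
#' @param refractory minimum separation between detections, seconds.
#' @param band band-pass edges in Hz.
#' @return a [SpikeEventTable-class].
#' @export
detectSpikes <- function(v, thresholdK = 5.5, refractory = 0.002,
                         band = c(300, 3000)) {
  stopifnot(inherits(v, "VoltageTrace") ||
              (is.list(v) && all(c("samples", "fs") %in% names(v))))
  fs <- v$fs
  if (fs <= 2 * band[2])
    stop("sampling rate must exceed twice the upper band edge",
         call. = FALSE)
  x <- v$samples
  if (!is.matrix(x)) x <- matrix(x, nrow = 1L)
  nS <- ncol(x)
  bf <- signal::butter(2, band / (fs / 2), type = "pass")
  warmup <- 3L * (length(bf$b) + length(bf$a))
  if (nS <= warmup)
    stop("trace shorter than the filter warm-up", call. = FALSE)
  ch <- integer(0); tm <- numeric(0)
  for (c in seq_len(nrow(x))) {
    f <- signal::filtfilt(bf, x[c, ])
    thr <- thresholdK * median(abs(f)) / 0.6745
    above <- abs(f) > thr
    if (!any(above)) next
    ix <- which(above)
    runStart <- c(TRUE, diff(ix) > 1L)
    runId <- cumsum(runStart)
    peaks <- vapply(split(ix, runId), function(run)
      run[which.max(abs(f[run]))], numeric(1))
    tDet <- enforceRefractory((peaks - 1) / fs, refractory)
    ch <- c(ch, rep.int(c - 1L, length(tDet)))
    tm <- c(tm, tDet)
  }
  makeEventTable(ch, tm, nrow(x), nS / fs,
                 metadata = list(thresholdK = thresholdK))
}

#' Select recording and stimulation electrodes by spike amplitude
#'
#' The `nRecord` electrodes with the highest spike amplitudes become
#' recording electrodes; of those, the `nStim` highest become stimulation
#' electrodes. Ties break toward the lower channel id.
#'
#' @param amplitudes per-electrode peak spike amplitude (position i is
#'   channel id i - 1).
#' @param nRecord number of recording electrodes (default 1024).
#' @param nStim number of stimulation electrodes (default 8).
#' @return list with 0-based `recording` and `stimulation` channel id
#'   vectors (amplitude-ranked).
#' @export
selectElectrodes <- function(amplitudes, nRecord = 1024L, nStim = 8L) {
  stopifnot(is.numeric(amplitudes), length(amplitudes) >= 1L)
  nRecord <- assertCount(nRecord, "nRecord", lower = 1L)
  nStim <- assertCount(nStim, "nStim", lower = 1L)
  if (length(amplitudes) < nRecord) {
    warning("fewer channels than requested recording electrodes; ",
            "taking all")
    nRecord <- length(amplitudes)
  }
  nStim <- min(nStim, nRecord)
  o <- order(-amplitudes, seq_along(amplitudes))
  rec <- o[seq_len(nRecord)] - 1L
  list(recording = rec, stimulation = rec[seq_len(nStim)])
}

#' Generate spike trains with planted pairwise correlations
#'
#' Fixture generator for connectivity studies: `nTrains` Poisson trains of
#' the given rate, with `nCorrelatedPairs` pairs (chained over randomly
#' chosen nodes) sharing a fraction of jittered common spikes, so the
#' planted pairs carry genuine millisecond-scale correlation on top of
#' independent background. Emulates the before/after-training contrast in
#' spontaneous recordings: more correlated pairs after training.
#'
#' @param nTrains number of trains (nodes).
#' @param duration recording length, seconds.
#' @param rate baseline rate, Hz.
#' @param nCorrelatedPairs number of node pairs given shared spikes.
#' @param sharedFraction fraction of each correlated train's spikes drawn
#'   from the pair's common source.
#' @param jitterSd sd of the Gaussian jitter on shared spikes, seconds.
#' @param seed integer seed.
#' @return list of sorted spike-time vectors.
#' @export
simulateCorrelatedTrains <- function(nTrains, duration, rate = 2,
                                     nCorrelatedPairs = 0L,
                                     sharedFraction = 0.5,
                                     jitterSd = 0.003, seed = 1L) {
  nTrains <- assertCount(nTrains, "nTrains", lower = 2L)
  duration <- assertNumber(duration, "duration", lower = 1e-9)
  nCorrelatedPairs <- assertCount(nCorrelatedPairs, "nCorrelatedPairs")
  set.seed(tagSeed(seed, "correlated-trains"))
  trains <- lapply(seq_len(nTrains), function(i)
    sort(runif(rpois(1L, rate * duration), 0, duration)))
  if (nCorrelatedPairs > 0L) {
    ij <- cbind(sample.int(nTrains, nCorrelatedPairs, replace = TRUE),
                sample.int(nTrains, nCorrelatedPairs, replace = TRUE))
    ij[ij[, 1L] == ij[, 2L], 2L] <-
      (ij[ij[, 1L] == ij[, 2L], 1L] %% nTrains) + 1L
    for (r in seq_len(nCorrelatedPairs)) {
      src <- sort(runif(rpois(1L, rate * duration * sharedFraction),
                        0, duration))
      for (node in ij[r, ]) {
        keep <- runif(length(trains[[node]])) > sharedFraction
        merged <- c(trains[[node]][keep],
                    src + rnorm(length(src), 0, jitterSd))
        trains[[node]] <- sort(pmin(pmax(merged, 0), duration))
      }
    }
  }
  trains
}
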