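#' Pipeline run configuration
#'
#' Nested configuration for the full encode-stimulate-record-decode study:
#' one global seed is fanned out to every stochastic component through
#' stable tags, so a single integer reproduces the whole run. The defaults
#' are desk-scale (64 recording channels, shortened connectivity
#' recordings); the per-module configs keep their own full-scale defaults.
#'
#' @param seed global integer seed.
#' @param nPerClass synthetic images generated per class; 3 per class
#'   become the 9 stimulus images, the rest train the extractor.
#' @param extractor an [extractorConfig()].
#' @param encoding an [encodingConfig()].
#' @param nChannels recording channels for the simulated network.
#' @param spontaneousRate,meanGain,plasticityDrift simulator headline
#'   parameters (see [simulatorConfig()] and [randomGainMatrix()]).
#' @param repetitions stimulations per program (50 in the staged
#'   protocol).
#' @param decoding a [decodingConfig()].
#' @param connectivityDuration spontaneous recording length (seconds) for
#'   the before/after connectivity analysis.
#' @param representativeK representative channels for the graph.
#' @param nSurrogates jitter surrogates for edge significance.
#' @param blank blank-control mode: the simulated chip carries no neurons
#'   and emits zero events.
#' @return list of class `RunConfig`.
#' @export
runConfig <- function(seed = 1L, nPerClass = 12L,
                      extractor = extractorConfig(maxEpochs = 12L),
                      encoding = encodingConfig(),
                      nChannels = 64L, spontaneousRate = 0.5,
                      meanGain = 0.5, plasticityDrift = 1.15,
                      repetitions = 50L,
                      decoding = decodingConfig(),
                      connectivityDuration = 60,
                      representativeK = 20L, nSurrogates = 50L,
                      blank = FALSE) {
  cfg <- list(seed = assertCount(seed, "seed"),
              nPerClass = assertCount(nPerClass, "nPerClass", lower = 4L),
              extractor = extractor, encoding = encoding,
              nChannels = assertCount(nChannels, "nChannels", lower = 8L),
              spontaneousRate = assertNumber(spontaneousRate,
                                             "spontaneousRate", lower = 0),
              meanGain = assertNumber(meanGain, "meanGain", lower = 0),
              plasticityDrift = assertNumber(plasticityDrift,
                                             "plasticityDrift", lower = 0),
              repetitions = assertCount(repetitions, "repetitions",
                                        lower = 20L),
              decoding = decoding,
              connectivityDuration = assertNumber(connectivityDuration,
                                                  "connectivityDuration",
                                                  lower = 1),
              representativeK = assertCount(representativeK,
                                            "representativeK", lower = 2L),
              nSurrogates = assertCount(nSurrogates, "nSurrogates",
                                        lower = 10L),
              blank = assertFlag(blank, "blank"))
  stopifnot(inherits(cfg$extractor, "ExtractorConfig"),
            inherits(cfg$encoding, "EncodingConfig"),
            inherits(cfg$decoding, "DecodingConfig"))
  class(cfg) <- "RunConfig"
  cfg
}

#' Run the full encode-stimulate-record-decode pipeline
#'
#' Generates synthetic images, trains the feature extractor, encodes 9
#' stimulus images (3 per class) into pulse programs, simulates the
#' staged stimulation session, runs the staged decoding protocol, and
#' performs the before/after functional-connectivity comparison on
#' spontaneous recordings (the "after" recording carries additional
#' correlated pairs when plasticity drift is on). Returns a JSON-ready
#' report; bit-identical for identical configs.
#'
#' @param cfg a [runConfig()].
#' @param outDir optional directory; when given, the report (JSON), the 9
#'   pulse programs and the graph edge lists are written there.
#' @return list of class `PipelineReport` (see fields in the JSON).
#' @export
runPipeline <- function(cfg = runConfig(), outDir = NULL) {
  stopifnot(inherits(cfg, "RunConfig"))
  seed <- cfg$seed
  ex <- cfg$extractor
  ex$seed <- tagSeed(seed, "extractor")
  imgs <- generateSyntheticImages(cfg$nPerClass, side = ex$inputSide,
                                  seed = tagSeed(seed, "images"))
  labs <- vapply(imgs, `[[`, character(1), "label")
  byClass <- split(seq_along(imgs), labs)
  stimIdx <- unlist(lapply(byClass, head, 3L))
  restIdx <- setdiff(seq_along(imgs), stimIdx)
  nVal <- max(1L, floor(length(restIdx) / 8))
  valIdx <- unlist(lapply(split(restIdx, labs[restIdx]), head, nVal))
  trainIdx <- setdiff(restIdx, valIdx)

  params <- trainFeatureExtractor(imgs[trainIdx], imgs[valIdx], ex)
  programs <- lapply(imgs[stimIdx], function(im)
    encodePulses(extractFeatures(im, params), cfg$encoding))

  gain <- randomGainMatrix(cfg$nChannels, meanGain = cfg$meanGain,
                           seed = tagSeed(seed, "gains"))
  sim <- simulatorConfig(nChannels = cfg$nChannels,
                         spontaneousRate = cfg$spontaneousRate,
                         gain = gain,
                         plasticityDrift = cfg$plasticityDrift)
  session <- simulateSession(programs, sim,
                             seed = tagSeed(seed, "session"),
                             repetitions = cfg$repetitions,
                             blank = cfg$blank)
  protocol <- evaluateProtocol(session, cfg$decoding, programs = programs)

  # before/after spontaneous connectivity; training adds correlated pairs
  k <- cfg$representativeK
  nPairsAfter <- if (cfg$blank || cfg$plasticityDrift <= 1) 0L else
    max(4L, k %/% 2L)
  mkGraph <- function(nPairs, tag) {
    trains <- simulateCorrelatedTrains(
      k, cfg$connectivityDuration, rate = 2, nCorrelatedPairs = nPairs,
      seed = tagSeed(seed, tag))
    buildConnectivityGraph(trains, cfg$connectivityDuration,
                           nSurrogates = cfg$nSurrogates,
                           seed = tagSeed(seed, paste0(tag, "-edges")))
  }
  gBefore <- consensusModules(mkGraph(0L, "conn-before"), nRuns = 50L,
                              seed = tagSeed(seed, "mod-before"))
  gAfter <- consensusModules(mkGraph(nPairsAfter, "conn-after"),
                             nRuns = 50L,
                             seed = tagSeed(seed, "mod-after"))
  comparison <- compareConditions(gBefore, gAfter)

  report <- list(
    seed = seed,
    configHash = configHash(rapply(unclass(cfg), unclass, how = "replace")),
    blank = cfg$blank,
    extractor = list(valAccuracy = params$valAccuracy,
                     valLoss = params$valLoss,
                     epochsRun = params$epochsRun),
    programs = list(
      pulseCounts = vapply(programs, function(p)
        sum(lengths(pulseTimes(p))), numeric(1)),
      meanPairwiseDistance = mean(
        utils::combn(length(programs), 2L, function(ij)
          sequenceDistance(pulseMatrix(programs[[ij[1]]]),
                           pulseMatrix(programs[[ij[2]]]))))),
    accuracyByStage = protocol$accuracyByStage,
    confusion = lapply(protocol[1:3], function(s)
      unclass(as.matrix(s$confusion))),
    connectivity = comparison)
  class(report) <- "PipelineReport"

  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_along(programs))
      writePulseProgram(programs[[i]],
                        file.path(outDir, sprintf("program-%d.json", i)))
    writeEdgeList(gBefore, file.path(outDir, "edges-before.csv"))
    writeEdgeList(gAfter, file.path(outDir, "edges-after.csv"))
    jsonlite::write_json(unclass(report),
                         file.path(outDir, "report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  report
}
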