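FORMAT_VERSION <- 1L

#' Write / read a SpikeEventTable as CSV with a metadata header
#'
#' Plain-text serialization: commented header lines carry the format
#' version, channel count, duration and the metadata as JSON, followed by
#' a `channel,time` CSV body. Reading validates the header and fails
#' loudly on truncated or foreign files.
#'
#' @param st a [SpikeEventTable-class].
#' @param path file path.
#' @return `writeSpikeEvents` returns `path` invisibly; `readSpikeEvents`
#'   returns the [SpikeEventTable-class].
#' @export
writeSpikeEvents <- function(st, path) {
  stopifnot(is(st, "SpikeEventTable"))
  validObject(st)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# bnncode-spike-events v%d", FORMAT_VERSION),
    sprintf("# nChannels=%d", st@nChannels),
    sprintf("# duration=%.17g", st@duration),
    sprintf("# metadata=%s", as.character(
      jsonlite::toJSON(st@metadata, auto_unbox = TRUE, digits = NA))),
    "channel,time"), con)
  ev <- spikeEvents(st)
  if (nrow(ev))
    writeLines(sprintf("%d,%.17g", ev$channel, ev$time), con)
  invisible(path)
}

#' @rdname writeSpikeEvents
#' @export
readSpikeEvents <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 5L || !startsWith(lines[1], "# bnncode-spike-events"))
    stop("not a bnncode spike-events file (bad or truncated header)",
         call. = FALSE)
  ver <- sub("^# bnncode-spike-events v", "", lines[1])
  if (as.integer(ver) != FORMAT_VERSION)
    stop("unsupported spike-events format version: ", ver, call. = FALSE)
  getField <- function(i, key) {
    if (!startsWith(lines[i], paste0("# ", key, "=")))
      stop("malformed spike-events header (missing ", key, ")",
           call. = FALSE)
    sub(paste0("^# ", key, "="), "", lines[i])
  }
  nCh <- as.integer(getField(2L, "nChannels"))
  dur <- as.numeric(getField(3L, "duration"))
  md <- jsonlite::fromJSON(getField(4L, "metadata"), simplifyVector = TRUE)
  if (lines[5] != "channel,time")
    stop("malformed spike-events body header", call. = FALSE)
  body <- lines[-(1:5)]
  body <- body[nzchar(body)]
  if (length(body)) {
    parts <- strsplit(body, ",", fixed = TRUE)
    if (any(lengths(parts) != 2L))
      stop("malformed spike-events row (truncated file?)", call. = FALSE)
    ch <- as.integer(vapply(parts, `[[`, character(1), 1L))
    tm <- as.numeric(vapply(parts, `[[`, character(1), 2L))
    if (any(is.na(ch)) || any(is.na(tm)))
      stop("unparseable spike-events row", call. = FALSE)
  } else {
    ch <- integer(0); tm <- numeric(0)
  }
  makeEventTable(ch, tm, nCh, dur, as.list(md))
}

#' Write / read a PulseProgram as JSON
#'
#' @param pp a [PulseProgram-class].
#' @param path file path.
#' @return `writePulseProgram` returns `path` invisibly;
#'   `readPulseProgram` the [PulseProgram-class].
#' @export
writePulseProgram <- function(pp, path) {
  stopifnot(is(pp, "PulseProgram"))
  validObject(pp)
  obj <- list(format = "bnncode-pulse-program", version = FORMAT_VERSION,
              window = pp@window, slotPeriod = pp@slotPeriod,
              pulseAmplitude = pp@pulseAmplitude,
              phaseDuration = pp@phaseDuration,
              provenance = pp@provenance,
              channels = lapply(pp@channels, as.numeric))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writePulseProgram
#' @export
readPulseProgram <- function(path) {
  obj <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e)
                    stop("unparseable pulse-program file: ",
                         conditionMessage(e), call. = FALSE))
  if (!identical(obj$format, "bnncode-pulse-program"))
    stop("not a bnncode pulse-program file", call. = FALSE)
  if (obj$version != FORMAT_VERSION)
    stop("unsupported pulse-program version", call. = FALSE)
  new("PulseProgram",
      channels = lapply(obj$channels, function(x) as.numeric(unlist(x))),
      window = obj$window, slotPeriod = obj$slotPeriod,
      pulseAmplitude = obj$pulseAmplitude,
      phaseDuration = obj$phaseDuration,
      provenance = lapply(obj$provenance, identity))
}

#' Write / read a PulseMatrix as CSV
#'
#' Plain 0/1 CSV, one row per stimulation channel, one column per
#' oscillation-peak slot.
#'
#' @param pm a [PulseMatrix-class].
#' @param path file path.
#' @param slotPeriod slot spacing attached on read (seconds).
#' @return `writePulseMatrix` returns `path` invisibly; `readPulseMatrix`
#'   the [PulseMatrix-class].
#' @export
writePulseMatrix <- function(pm, path) {
  stopifnot(is(pm, "PulseMatrix"))
  write.table(pulseBits(pm), path, sep = ",", row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @rdname writePulseMatrix
#' @export
readPulseMatrix <- function(path, slotPeriod = 0.2) {
  m <- as.matrix(read.csv(path, header = FALSE))
  storage.mode(m) <- "integer"
  dimnames(m) <- NULL
  new("PulseMatrix", bits = m, slotPeriod = slotPeriod)
}

#' Export a connectivity graph
#'
#' `writeEdgeList` writes the kept edges as `i,j,sttc` CSV (0-based
#' channel ids); `writeGraphML` exports the weighted graph (with node
#' coordinates and modules when present) in GraphML for external tools.
#'
#' @param g a [ConnectivityGraph-class].
#' @param path file path.
#' @return the path, invisibly.
#' @export
writeEdgeList <- function(g, path) {
  stopifnot(is(g, "ConnectivityGraph"))
  ut <- which(upper.tri(g@adjacency) & g@adjacency == 1, arr.ind = TRUE)
  df <- data.frame(i = g@nodes[ut[, 1L]], j = g@nodes[ut[, 2L]],
                   sttc = g@weights[ut])
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeEdgeList
#' @export
writeGraphML <- function(g, path) {
  stopifnot(is(g, "ConnectivityGraph"))
  ig <- igraph::graph_from_adjacency_matrix(g@weights, weighted = TRUE,
                                            mode = "undirected",
                                            diag = FALSE)
  igraph::V(ig)$channel <- g@nodes
  igraph::V(ig)$x <- g@coords[, 1L]
  igraph::V(ig)$y <- g@coords[, 2L]
  if (length(g@partition)) igraph::V(ig)$module <- g@partition
  igraph::write_graph(ig, path, format = "graphml")
  invisible(path)
}

#' Save / load a trained decoder as JSON
#'
#' @param decoder a [TrainedDecoder-class].
#' @param path file path.
#' @return `saveDecoder` returns `path` invisibly; `loadDecoder` the
#'   [TrainedDecoder-class].
#' @export
saveDecoder <- function(decoder, path) {
  stopifnot(is(decoder, "TrainedDecoder"))
  obj <- list(format = "bnncode-decoder", version = FORMAT_VERSION,
              center = decoder@center,
              rotation = decoder@rotation,
              rotationDim = dim(decoder@rotation),
              beta = decoder@beta, betaDim = dim(decoder@beta),
              classes = decoder@classes,
              lossTrace = decoder@lossTrace,
              converged = decoder@converged)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname saveDecoder
#' @export
loadDecoder <- function(path) {
  obj <- tryCatch(jsonlite::fromJSON(path, simplifyVector = TRUE),
                  error = function(e)
                    stop("unparseable decoder file: ",
                         conditionMessage(e), call. = FALSE))
  if (!identical(obj$format, "bnncode-decoder"))
    stop("not a bnncode decoder file", call. = FALSE)
  new("TrainedDecoder",
      center = as.numeric(obj$center),
      rotation = matrix(as.numeric(obj$rotation), obj$rotationDim[1],
                        obj$rotationDim[2]),
      beta = matrix(as.numeric(obj$beta), obj$betaDim[1], obj$betaDim[2]),
      classes = as.character(obj$classes),
      lossTrace = as.numeric(obj$lossTrace),
      converged = as.logical(obj$converged))
}

#' Save / load trained extractor parameters as JSON
#'
#' Serializes the conv/pool stack weights with the training configuration
#' embedded, so a saved extractor reproduces features exactly.
#'
#' @param params `ExtractorParams` from [trainFeatureExtractor()].
#' @param path file path.
#' @return `saveExtractor` returns `path` invisibly; `loadExtractor` the
#'   `ExtractorParams`.
#' @export
saveExtractor <- function(params, path) {
  stopifnot(inherits(params, "ExtractorParams"))
  obj <- list(format = "bnncode-extractor", version = FORMAT_VERSION,
              conv = lapply(params$conv, function(l)
                list(W = as.numeric(l$W), dim = dim(l$W),
                     b = as.numeric(l$b))),
              fc = list(W = as.numeric(params$fc$W),
                        dim = dim(params$fc$W),
                        b = as.numeric(params$fc$b)),
              config = unclass(params$config),
              classes = params$classes,
              valLoss = params$valLoss, valAccuracy = params$valAccuracy,
              epochsRun = params$epochsRun)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname saveExtractor
#' @export
loadExtractor <- function(path) {
  obj <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e)
                    stop("unparseable extractor file: ",
                         conditionMessage(e), call. = FALSE))
  if (!identical(obj$format, "bnncode-extractor"))
    stop("not a bnncode extractor file", call. = FALSE)
  conv <- lapply(obj$conv, function(l)
    list(W = array(as.numeric(unlist(l$W)), as.integer(unlist(l$dim))),
         b = as.numeric(unlist(l$b))))
  co <- lapply(obj$config, unlist)
  cfg <- extractorConfig(filters = as.integer(co$filters),
                         inputSide = co$inputSide,
                         learningRate = co$learningRate,
                         maxEpochs = co$maxEpochs, patience = co$patience,
                         batchSize = co$batchSize, seed = co$seed)
  fcDim <- as.integer(unlist(obj$fc$dim))
  structure(list(conv = conv,
                 fc = list(W = matrix(as.numeric(unlist(obj$fc$W)),
                                      fcDim[1], fcDim[2]),
                           b = as.numeric(unlist(obj$fc$b))),
                 config = cfg,
                 classes = as.character(unlist(obj$classes)),
                 valLoss = obj$valLoss, valAccuracy = obj$valAccuracy,
                 epochsRun = obj$epochsRun),
            class = "ExtractorParams")
}

#' Write / read an image as PNG
#'
#' @param img image list (field `pixels`) or H x W x 3 array in \[0, 1\].
#' @param path file path.
#' @return `writeImagePNG` returns `path` invisibly; `readImagePNG` an
#'   image list with `pixels` and `id` (the file stem).
#' @export
writeImagePNG <- function(img, path) {
  px <- if (is.list(img)) img$pixels else img
  png::writePNG(px, path)
  invisible(path)
}

#' @rdname writeImagePNG
#' @export
readImagePNG <- function(path) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 2L) px <- array(rep(px, 3L), c(dim(px), 3L))
  if (dim(px)[3] > 3L) px <- px[, , 1:3, drop = FALSE]
  list(pixels = px, label = NA_character_,
       id = sub("\\.png$", "", basename(path)))
}
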