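test_that("spontaneous counts follow the Poisson law channel-wise", {
  cfg <- simulatorConfig(nChannels = 200L, spontaneousRate = 1,
                         burstRate = 0)
  st <- simulateSpontaneous(100, cfg, seed = 21)
  counts <- tabulate(spikeEvents(st)$channel + 1L, nbins = 200L)
  # 4-sigma Poisson tail bound at lambda = 100 (refractory loss ~0.2%)
  inBand <- abs(counts - 100) <= 4 * sqrt(100)
  expect_gte(mean(inBand), 0.99)
  # refractory respected
  byCh <- split(spikeEvents(st)$time, spikeEvents(st)$channel)
  gaps <- unlist(lapply(byCh, function(t) diff(sort(t))))
  expect_true(all(gaps >= 0.002 - 1e-12))
})

test_that("silent configurations and determinism behave as stated", {
  quiet <- simulatorConfig(nChannels = 16L, spontaneousRate = 0,
                           burstRate = 0)
  st <- simulateSpontaneous(10, quiet, seed = 1)
  expect_equal(nrow(spikeEvents(st)), 0)
  cfg <- simulatorConfig(nChannels = 16L)
  a <- simulateSpontaneous(5, cfg, seed = 33)
  b <- simulateSpontaneous(5, cfg, seed = 33)
  expect_identical(spikeEvents(a), spikeEvents(b))
  expect_error(simulateSpontaneous(0, cfg), "duration")
})

test_that("zero-gain evoked activity reduces to the spontaneous model", {
  cfg <- simulatorConfig(nChannels = 64L, spontaneousRate = 1,
                         burstRate = 0)
  pp <- randomPrograms(1, seed = 2)[[1]]
  nEv <- nrow(spikeEvents(simulateEvoked(pp, cfg, seed = 4)))
  nSp <- nrow(spikeEvents(simulateSpontaneous(pp@window, cfg, seed = 5)))
  # both are Poisson(128); a two-sample rate test must not reject
  expect_gt(stats::poisson.test(c(nEv, nSp), c(1, 1))$p.value, 0.01)
})

test_that("evoked spikes are causal and recover the programmed gain", {
  cfg <- simulatorConfig(nChannels = 4L, spontaneousRate = 0,
                         burstRate = 0,
                         gain = matrix(2, 8, 4))
  pp <- randomPrograms(1, seed = 3)[[1]]
  st <- simulateEvoked(pp, cfg, seed = 6)
  first <- min(unlist(pulseTimes(pp)))
  expect_true(all(spikeEvents(st)$time > first + cfg$latency - 1e-12))

  # mean extra count per trial for a single pulse with gain 3
  g <- matrix(0, 8, 1); g[1, 1] <- 3
  cfg1 <- simulatorConfig(nChannels = 1L, spontaneousRate = 0,
                          burstRate = 0, gain = g)
  one <- new("PulseProgram", channels = c(list(0), rep(list(numeric(0)),
                                                       7)))
  counts <- vapply(seq_len(10000), function(r)
    nrow(spikeEvents(simulateEvoked(one, cfg1, seed = r))), numeric(1))
  expect_lt(abs(mean(counts) - 3), 3 * sqrt(3 / 10000))
  # post-stimulus rate has recovered by 0.2 s (tau = 50 ms kernel)
  late <- vapply(seq_len(200), function(r) {
    ev <- spikeEvents(simulateEvoked(one, cfg1, seed = 20000 + r))
    sum(ev$time > 0.2)
  }, numeric(1))
  expect_lt(mean(late), 3 * exp(-0.2 / 0.05) + 3 * sqrt(3 / 200))
})

test_that("the staged session carries the protocol bookkeeping", {
  progs <- randomPrograms(9, seed = 5)
  cfg <- simulatorConfig(nChannels = 8L, spontaneousRate = 0.2,
                         burstRate = 0)
  ses <- simulateSession(progs, cfg, seed = 9)
  expect_length(ses$evoked, 450)
  expect_length(ses$spontaneous, 50)
  md <- lapply(ses$evoked, recordingMetadata)
  stim <- vapply(md, `[[`, numeric(1), "stimulus")
  stage <- vapply(md, function(m) m$stage %||% NA_integer_, numeric(1))
  test <- vapply(md, function(m) m$testStage %||% NA_integer_, numeric(1))
  for (s in 1:9) {
    expect_equal(unname(table(stage[stim == s])), c(15, 15, 15),
                 ignore_attr = TRUE)
    expect_equal(sum(!is.na(test[stim == s])), 15)
    expect_equal(unname(table(test[stim == s])), c(5, 5, 5),
                 ignore_attr = TRUE)
  }
  expect_error(simulateSession(progs[1:5], cfg), "9 pulse programs")

  blank <- simulateSession(progs, cfg, seed = 9, blank = TRUE)
  expect_true(all(vapply(blank$evoked, function(t)
    nrow(spikeEvents(t)) == 0, logical(1))))
})

test_that("synthesized voltage has the requested noise floor", {
  cfg <- simulatorConfig(nChannels = 1L, spontaneousRate = 0,
                         burstRate = 0)
  st <- simulateSpontaneous(1, cfg, seed = 2)   # empty
  v <- synthesizeVoltage(st, fs = 20000, noiseSd = 8, seed = 3)
  expect_equal(v$eventCount, 0)
  expect_lt(abs(sd(v$samples[1, ]) - 8) / 8, 0.05)
})

test_that("spike detection controls false positives and recovers spikes", {
  # pure noise: threshold-crossing rate at 5.5 sigma is far below 1 Hz
  cfg <- simulatorConfig(nChannels = 2L, spontaneousRate = 0,
                         burstRate = 0)
  empty <- simulateSpontaneous(10, cfg, seed = 4)
  v <- synthesizeVoltage(empty, fs = 20000, noiseSd = 8, seed = 5)
  det <- detectSpikes(v)
  expect_lt(nrow(spikeEvents(det)) / 10 / 2, 1)

  # 100 well-separated spikes at 12x noise sd: >= 95 within +/- 1 ms
  times <- seq(0.05, 9.95, length.out = 100)
  st <- bnncode:::makeEventTable(rep(0L, 100), times, 1L, 10)
  v2 <- synthesizeVoltage(st, fs = 20000, noiseSd = 8,
                          spikeAmplitude = 96, seed = 6)
  det2 <- detectSpikes(v2)
  hits <- vapply(times, function(t0)
    any(abs(spikeEvents(det2)$time - t0) <= 1e-3), logical(1))
  expect_gte(sum(hits), 95)

  # short but valid trace: no crash, >= 0 events
  short <- synthesizeVoltage(bnncode:::makeEventTable(integer(0),
                                                      numeric(0), 1L, 0.1),
                             fs = 20000, seed = 7)
  expect_gte(nrow(spikeEvents(detectSpikes(short))), 0)
  tiny <- list(samples = matrix(rnorm(10), 1), fs = 20000)
  class(tiny) <- "VoltageTrace"
  expect_error(detectSpikes(tiny), "warm-up")
})

test_that("electrode selection ranks amplitudes with stable ties", {
  amp <- seq_len(26400)                    # identity permutation
  sel <- selectElectrodes(amp)
  expect_equal(sort(sel$recording), 25376:26399)
  expect_length(sel$stimulation, 8)
  expect_true(all(sel$stimulation %in% sel$recording))
  expect_equal(sel$stimulation, 26399:26392)

  expect_warning(s2 <- selectElectrodes(c(3, 1, 2), nRecord = 10,
                                        nStim = 2), "fewer")
  expect_equal(sort(s2$recording), 0:2)
  expect_equal(s2$stimulation, c(0L, 2L))

  tied <- selectElectrodes(c(5, 5, 5, 1), nRecord = 2, nStim = 1)
  expect_equal(tied$recording, c(0L, 1L))  # ties to the lower id
})
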