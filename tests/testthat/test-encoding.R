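cfgDef <- encodingConfig()

test_that("the spike-timing function matches hand-computed latencies", {
  expect_equal(spikeTime(0), 1)
  expect_equal(spikeTime(1), 0, tolerance = 1e-12)
  # 1 - atan(tan(1) * 0.5), frozen from high-precision evaluation
  expect_equal(spikeTime(0.5), 0.3383800681498235, tolerance = 1e-9)
  p <- seq(0, 1, by = 0.01)
  expect_true(all(diff(spikeTime(p)) < 0))       # strictly decreasing
  expect_true(all(spikeTime(p) >= 0 & spikeTime(p) <= 1))
  expect_error(spikeTime(1.2), "\\[0, 1\\]")
  # a steeper curve would go negative; the clamp keeps times at 0
  steep <- encodingConfig(delta = 10)
  expect_equal(spikeTime(1, steep), 0)
})

test_that("positional delays are exact fractions of the delay span", {
  expect_identical(positionDelay(0), 0)
  expect_equal(positionDelay(5), 0.2)
  expect_equal(positionDelay(24), 0.96)
  expect_error(positionDelay(25), "\\[0, 25\\)")
  expect_error(positionDelay(-1), "\\[0, 25\\)")
})

test_that("oscillation-peak alignment snaps to nearest peak, ties earlier", {
  expect_equal(smoAlign(0.29), 0.2)
  expect_equal(smoAlign(0.3), 0.2)      # exact tie -> earlier peak
  expect_equal(smoAlign(0.5), 0.4)      # another half-way point
  expect_equal(smoAlign(1.97), 1.8)     # beyond last peak clamps to it
  set.seed(3)
  t <- runif(500, 0, 2)
  a <- smoAlign(t)
  expect_true(all(abs(a / 0.2 - round(a / 0.2)) < 1e-12))
  expect_true(all(a >= 0 & a <= 1.8))
  expect_error(smoAlign(2.5), "window")
})

test_that("a zero map with the floor disabled fills the late slots", {
  fm <- new("FeatureMapSet", maps = array(0, c(5, 5, 8)))
  pp <- encodePulses(fm, encodingConfig(significanceFloor = 0))
  # raw times 1.0 + i/25 spread over [1.0, 1.96]; aligned peaks 1.0..1.8
  for (ch in 1:8) {
    expect_equal(pulseTimes(pp)[[ch]], c(1.0, 1.2, 1.4, 1.6, 1.8))
    expect_lte(length(pulseTimes(pp)[[ch]]), 6)
  }
  # with the default floor the zero map emits nothing
  pp2 <- encodePulses(fm)
  expect_true(all(lengths(pulseTimes(pp2)) == 0))
})

test_that("encoded programs always satisfy the stimulation constraints", {
  for (seed in 1:20) {
    pp <- encodePulses(randomFeatureMapSet(seed), cfgDef)
    times <- pulseTimes(pp)
    expect_length(times, 8)
    for (t in times) {
      if (!length(t)) next
      expect_true(all(t >= 0 & t <= 2))
      expect_true(all(abs(t / 0.2 - round(t / 0.2)) < 1e-9))
      if (length(t) > 1) expect_true(all(diff(t) >= 0.2 - 1e-9))
      # compression bound and implied 5 Hz rate cap
      expect_lte(length(t), 10)
      expect_lte(length(t) / 2, 5)
    }
    expect_identical(pulseTimes(encodePulses(randomFeatureMapSet(seed),
                                             cfgDef)), times)
  }
})

test_that("the binary matrix view is faithful and invertible", {
  empty <- new("PulseProgram")
  expect_true(all(pulseBits(pulseMatrix(empty)) == 0))
  expect_equal(dim(pulseBits(pulseMatrix(empty))), c(8L, 10L))

  one <- new("PulseProgram",
             channels = c(rep(list(numeric(0)), 3), list(0.4),
                          rep(list(numeric(0)), 4)))
  bits <- pulseBits(pulseMatrix(one))
  expect_equal(sum(bits), 1)
  expect_equal(bits[4, 3], 1L)   # 0-based: channel 3, slot 2

  set.seed(8)
  for (r in 1:10) {
    bits <- matrix(as.integer(runif(80) < 0.35), 8, 10)
    pm <- new("PulseMatrix", bits = bits, slotPeriod = 0.2)
    back <- pulseMatrix(pulseProgramFromMatrix(pm))
    expect_identical(pulseBits(back), pulseBits(pm))
  }
})

test_that("sequence distance is the Euclidean metric on binary matrices", {
  u <- matrix(1, 8, 10)
  expect_equal(sequenceDistance(u, u), 0)
  expect_equal(sequenceDistance(u, matrix(0, 8, 10)), sqrt(80))
  v <- u; v[1, 1:9] <- 0
  expect_equal(sequenceDistance(u, v), 3)
  expect_error(sequenceDistance(u, matrix(0, 8, 9)), "equal shape")
  set.seed(4)
  for (r in 1:25) {
    a <- matrix(rbinom(80, 1, 0.5), 8, 10)
    b <- matrix(rbinom(80, 1, 0.5), 8, 10)
    cc <- matrix(rbinom(80, 1, 0.5), 8, 10)
    expect_equal(sequenceDistance(a, b), sequenceDistance(b, a))
    expect_gte(sequenceDistance(a, b), 0)
    expect_lte(sequenceDistance(a, cc),
               sequenceDistance(a, b) + sequenceDistance(b, cc) + 1e-12)
    if (!identical(a, b)) expect_gt(sequenceDistance(a, b), 0)
  }
})

test_that("invalid encoding configurations are rejected", {
  expect_error(encodingConfig(smoPeriod = 0.1, minInterval = 0.2),
               "minInterval")
  expect_error(encodingConfig(window = 1.9), "multiple")
})
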