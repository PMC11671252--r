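test_that("DPSS tapers are orthonormal and concentrated", {
  v <- dpssTapers(200, 4, 6)
  expect_equal(dim(v), c(200, 6))
  expect_equal(crossprod(v), diag(6), tolerance = 1e-8)
  # leading taper concentrates its energy inside |f| <= W = nw/n
  V <- mvfft(rbind(v, matrix(0, 1848, 6)))
  p <- Mod(V)^2
  W <- 4 / 200
  inBand <- (0:2047) / 2048 <= W | (0:2047) / 2048 >= 1 - W
  conc <- colSums(p[inBand, ]) / colSums(p)
  expect_gt(conc[1], 0.999)
  expect_true(all(diff(conc) < 1e-6))   # concentration non-increasing
  expect_error(dpssTapers(100, 4, 8), "2 \\* nw - 1")
})

test_that("decomposition grids follow the closed-form counts", {
  ep <- noiseSession(nTrials = 2, fs = 500, window = c(-0.7, 4),
                     grid = makeGrid(1, 2, arrayId = "x"), seed = 4)
  hi <- multitaperTFR(ep, 0.4, 0.05, 6, 4, c(1.5, 150))
  expect_length(hi@freqs, 76)
  expect_length(hi@times, 87)
  lo <- multitaperTFR(ep, 0.5, 0.25, 6, 4, freqList = c(3, 8, 12, 16, 58, 89))
  expect_length(lo@freqs, 6)
  expect_length(lo@times, 17)
  dec <- multitaperTFR(ep, 0.5, 0.35, 6, 4, c(1.5, 150))
  expect_length(dec@times, 13)
  # counts are a pure function of (span, fs, window, step)
  for (p in list(c(0.4, 0.05), c(0.5, 0.25), c(0.5, 0.35), c(0.3, 0.1))) {
    got <- length(multitaperTFR(ep, p[1], p[2], 3, 2, c(2, 100))@times)
    ns <- length(epochTimes(ep))
    expect_equal(got, floor((ns - round(p[1] * 500)) / round(p[2] * 500)) + 1)
  }
})

test_that("a pure tone peaks at its own frequency bin in every window", {
  fs <- 500
  tms <- seq(-0.5, 1.5, by = 1 / fs)
  dat <- array(rep(sin(2 * pi * 40 * tms), each = 2), c(2, 1, length(tms)))
  ep <- epochsFromArray(dat, fs = fs, t0 = -0.5)
  tfr <- multitaperTFR(ep, 0.4, 0.1, 6, 4, c(1.5, 150))
  binSpacing <- diff(tfr@freqs[1:2])
  for (w in seq_along(tfr@times))
    expect_lt(abs(tfr@freqs[which.max(tfr@power[1, 1, , w])] - 40),
              binSpacing)
})

test_that("frequency requests beyond Nyquist are rejected", {
  ep <- noiseSession(nTrials = 2, fs = 100, window = c(0, 2),
                     grid = makeGrid(1, 2, arrayId = "x"))
  expect_error(multitaperTFR(ep, 0.5, 0.25, 3, 2, c(2, 80)), "Nyquist")
  expect_error(multitaperTFR(ep, 0.5, 0.25, 3, 2, freqList = 60), "Nyquist")
})

test_that("baseline normalization maps power ratios to decibels", {
  # hand-built raw decomposition: trial x channel x freq x time
  power <- array(1, c(3, 2, 4, 10))
  power[, , 2, 6:10] <- 10     # x10 after "stimulus onset" at t = 0
  power[, , 3, 6:10] <- 100
  tfr <- new("SpectralPerturbation", power = power, freqs = c(4, 8, 16, 32),
             times = seq(-0.45, 0.45, by = 0.1), params = list(),
             normalized = FALSE, baselineWindow = numeric(0))
  out <- baselineNormalize(tfr, baselineWindow = c(-0.45, -0.05))
  expect_true(out@normalized)
  expect_equal(dim(out@power), c(2, 4, 10))
  expect_equal(out@power[1, 2, 7], 10)
  expect_equal(out@power[2, 3, 7], 20)
  expect_equal(out@power[1, 1, 7], 0)
  expect_lt(max(abs(out@power[, , 1:5])), 1e-12)
  badPower <- power; badPower[1, 1, 1, 1:5] <- 0
  bad <- new("SpectralPerturbation", power = badPower, freqs = c(4, 8, 16, 32),
             times = tfr@times, params = list(), normalized = FALSE,
             baselineWindow = numeric(0))
  expect_error(baselineNormalize(bad, c(-0.45, -0.05)), "zero baseline")
})

test_that("a stationary process has a flat, roughly 0 dB perturbation", {
  ep <- noiseSession(nTrials = 40, fs = 250, window = c(-0.5, 0.5),
                     grid = makeGrid(1, 2, arrayId = "x"), seed = 9)
  tfr <- multitaperTFR(ep, 0.2, 0.1, 3, 2, c(5, 100))
  ersp <- baselineNormalize(tfr, c(-0.5, 0))
  expect_lt(max(abs(ersp@power)), 1.5)        # dB, within estimator noise
  expect_lt(abs(mean(ersp@power)), 0.3)
  # white-noise multitaper power is flat across frequency
  spec <- apply(tfr@power, 3, mean)
  expect_lt(diff(range(spec)) / mean(spec), 0.25)
})
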