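makeRaw <- function(wave, fs = 2000, window = c(-0.7, 1.3), nch = 1) {
  tms <- seq(window[1], window[2], by = 1 / fs)
  dat <- array(0, c(1, nch, length(tms)))
  for (ch in seq_len(nch)) dat[1, ch, ] <- wave(tms)
  epochsFromArray(dat, fs = fs, t0 = window[1],
                  labels = factor("animate", levels = c("animate", "inanimate")))
}

test_that("conditioning preserves the passband within 1 dB", {
  ep <- makeRaw(function(t) sin(2 * pi * 10 * t))
  out <- conditionSignal(ep, filterSpec())
  expect_equal(samplingRate(out), 500)
  mid <- which(out@times > -0.4 & out@times < 1.0)
  ref <- sin(2 * pi * 10 * out@times)
  ratio <- sd(out@data[1, 1, mid]) / sd(ref[mid])
  expect_lt(abs(20 * log10(ratio)), 1)
  expect_gt(cor(out@data[1, 1, mid], ref[mid]), 0.999)
})

test_that("conditioning rejects DC and attenuates the stopband by > 20 dB", {
  # a 1 Hz zero-phase FIR high-pass needs a realistic epoch length
  ep <- makeRaw(function(t) 5 + sin(2 * pi * 300 * t), window = c(-0.7, 4))
  out <- conditionSignal(ep, filterSpec())
  mid <- which(out@times > -0.4 & out@times < 3.6)
  expect_lt(abs(mean(out@data[1, 1, mid])), 0.05)   # DC offset 5 -> ~0
  atten <- 20 * log10(sd(out@data[1, 1, mid]) / (1 / sqrt(2)))
  expect_lt(atten, -20)
})

test_that("the conditioning chain is linear", {
  a <- makeRaw(function(t) sin(2 * pi * 7 * t))
  b <- makeRaw(function(t) 0.5 * sin(2 * pi * 23 * t + 1))
  ab <- a; ab@data <- a@data + b@data
  ca <- conditionSignal(a)@data
  cb <- conditionSignal(b)@data
  cab <- conditionSignal(ab)@data
  expect_equal(cab, ca + cb, tolerance = 1e-8)
})

test_that("too-short epochs are rejected before filtering", {
  ep <- makeRaw(function(t) t, fs = 2000, window = c(0, 0.05))
  expect_error(conditionSignal(ep), "warm-up")
})

test_that("common-average re-referencing zeroes the array mean", {
  g <- combineGrids(makeGrid(2, 2, arrayId = "A"),
                    makeGrid(2, 2, arrayId = "B"))
  ep <- noiseSession(nTrials = 4, fs = 100, window = c(0, 0.5), grid = g,
                     seed = 3)
  out <- rereferenceCommonAverage(ep)
  for (chs in list(1:4, 5:8)) {
    avg <- apply(out@data[, chs, ], c(1, 3), mean)
    expect_lt(max(abs(avg)), 1e-12)
  }
  # idempotent
  out2 <- rereferenceCommonAverage(out)
  expect_equal(out2@data, out@data, tolerance = 1e-12)
})

test_that("re-referencing follows the mean algebra and array independence", {
  g <- combineGrids(makeGrid(2, 2, arrayId = "A"),
                    makeGrid(2, 2, arrayId = "B"))
  dat <- array(0, c(1, 8, 10))
  dat[1, 1, ] <- 1                          # signal on one channel of A
  dat[1, 5:8, ] <- rnorm(40)                # arbitrary content on B
  ep <- epochsFromArray(dat, fs = 100, grid = g,
                        labels = factor("animate",
                                        levels = c("animate", "inanimate")))
  out <- rereferenceCommonAverage(ep)
  expect_equal(out@data[1, 1, ], rep(1 - 1 / 4, 10))
  expect_equal(out@data[1, 2, ], rep(-1 / 4, 10))
  # identical signal on all channels of an array cancels entirely
  dat2 <- dat; dat2[1, 1:4, ] <- 1
  ep2 <- epochsFromArray(dat2, fs = 100, grid = g,
                         labels = ep@labels)
  out2 <- rereferenceCommonAverage(ep2)
  expect_lt(max(abs(out2@data[1, 1:4, ])), 1e-12)
  # array B is unaffected by what happens on A
  expect_equal(out2@data[1, 5:8, ], out@data[1, 5:8, ])
  expect_error(rereferenceCommonAverage(ep, makeGrid(1, 1, arrayId = "solo")),
               "single channel")
})

test_that("bipolar derivation references the dorsal neighbour, ventral at the edge", {
  g <- makeGrid(3, 2, arrayId = "A")
  dat <- array(rnorm(1 * 6 * 20), c(1, 6, 20))
  ep <- epochsFromArray(dat, fs = 100, grid = g,
                        labels = factor("animate",
                                        levels = c("animate", "inanimate")))
  # channel 3 is (2, 1): dorsal neighbour is (1, 1) = channel 1
  # channel 1 is (1, 1), dorsal end: ventral neighbour (2, 1) = channel 3
  bp <- bipolarDerive(ep, c(3, 1), g)
  expect_equal(attr(bp, "references"), c(1L, 3L))
  expect_equal(bp@data[1, 1, ], dat[1, 3, ] - dat[1, 1, ])
  expect_equal(bp@data[1, 2, ], dat[1, 1, ] - dat[1, 3, ])
  # common signal on both members cancels
  datc <- dat; datc[1, 1, ] <- datc[1, 3, ]
  epc <- epochsFromArray(datc, fs = 100, grid = g, labels = ep@labels)
  bpc <- bipolarDerive(epc, 3, g)
  expect_lt(max(abs(bpc@data)), 1e-12)
  # neighbour silent: derived equals the site signal
  dats <- array(0, c(1, 6, 20)); dats[1, 3, ] <- dat[1, 3, ]
  eps <- epochsFromArray(dats, fs = 100, grid = g, labels = ep@labels)
  expect_equal(bipolarDerive(eps, 3, g)@data[1, 1, ], dat[1, 3, ])
  expect_error(bipolarDerive(ep, 1, makeGrid(1, 4, arrayId = "flat")),
               "single row")
})
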