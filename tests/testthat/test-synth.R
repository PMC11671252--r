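test_that("identical configurations give bit-identical sessions", {
  cfg <- synthConfig(nTrials = 6, fs = 200, epochWindow = c(-0.1, 0.4),
                     grid = makeGrid(2, 2, arrayId = "x"),
                     effects = list(effectSpec(1, c(10, 30), c(0, 0.3))),
                     seed = 42)
  a <- simulateSession(cfg)
  b <- simulateSession(cfg)
  expect_identical(a@data, b@data)
  expect_identical(a@labels, b@labels)
  c2 <- simulateSession(synthConfig(nTrials = 6, fs = 200,
                                    epochWindow = c(-0.1, 0.4),
                                    grid = makeGrid(2, 2, arrayId = "x"),
                                    seed = 43))
  expect_false(identical(a@data, c2@data))
})

test_that("session structure matches the configuration", {
  ep <- noiseSession(nTrials = 10, fs = 250, window = c(-0.2, 0.6))
  expect_s4_class(ep, "TrialEpochs")
  expect_equal(nTrials(ep), 10)
  expect_equal(length(epochTimes(ep)), 0.8 * 250 + 1)
  expect_equal(as.vector(table(trialLabels(ep))), c(5, 5))
  # background noise at the configured floor
  expect_equal(sd(ep@data), 1, tolerance = 0.05)
})

test_that("invalid generator configurations are rejected", {
  g <- makeGrid(2, 2, arrayId = "x")
  unstable <- array(1.2, c(1, 1, 1))
  expect_error(synthConfig(grid = g, var = varSpec(1, unstable), seed = 1),
               "unstable VAR")
  expect_error(synthConfig(fs = 100, grid = g,
                           effects = list(effectSpec(1, c(40, 80), c(0, 1))),
                           seed = 1),
               "Nyquist")
  expect_error(synthConfig(grid = g,
                           effects = list(effectSpec(9, c(5, 10), c(0, 1))),
                           seed = 1),
               "subset of the grid")
  expect_error(varSpec(1:2, coupledVar(), sigma = matrix(0, 2, 2)),
               "positive definite")
})

test_that("planted band effects modulate power in band, window and category", {
  ep <- effectSession(nTrials = 30, channels = 1, band = c(30, 60),
                      window = c(0.1, 0.5), power = c(animate = 6, inanimate = 1),
                      amplitude = 2, fs = 250, epochWindow = c(-0.2, 0.8),
                      seed = 7)
  tfr <- multitaperTFR(ep, windowS = 0.2, stepS = 0.1, nTapers = 3,
                       timeBandwidth = 2, freqRange = c(2, 120))
  anim <- trialLabels(ep) == "animate"
  inBand <- tfr@freqs >= 30 & tfr@freqs <= 60
  inWin <- tfr@times > 0.15 & tfr@times < 0.45
  pa <- mean(tfr@power[anim, 1, inBand, inWin])
  pi_ <- mean(tfr@power[!anim, 1, inBand, inWin])
  expect_gt(pa / pi_, 1.5)                       # category contrast
  expect_gt(pa, mean(tfr@power[anim, 1, inBand, tfr@times < 0]) * 2)  # windowed
  expect_lt(mean(tfr@power[anim, 2, inBand, inWin]) /
            mean(tfr@power[!anim, 2, inBand, inWin]), 1.3)  # untouched channel
})

test_that("analytic VAR GC: independent channels have zero influence", {
  A <- array(0, c(2, 2, 1)); diag(A[, , 1]) <- c(0.4, 0.6)
  g <- analyticVarGC(varSpec(1:2, A), fs = 250, nfft = 128)
  expect_lt(max(g@gc[1, 2, ]), 1e-10)
  expect_lt(max(g@gc[2, 1, ]), 1e-10)
})

test_that("analytic bivariate GC matches the hand-derived value at DC", {
  # x_t = .5 x_{t-1} + e;  y_t = .2 y_{t-1} + .5 x_{t-1} + f, unit noise
  # H(0) = [[2, 0], [1.25, 1.25]], S_yy(0) = 3.125, intrinsic 1.5625,
  # so F(0) = log(2)
  g <- analyticVarGC(varSpec(1:2, coupledVar(0.5)), fs = 500, nfft = 256,
                     type = "pairwise")
  expect_equal(g@gc[1, 2, 1], log(2), tolerance = 1e-10)
  expect_lt(max(g@gc[2, 1, ]), 1e-10)
  # conditional path (empty conditioning) agrees with the closed form
  gc2 <- analyticVarGC(varSpec(1:2, coupledVar(0.5)), fs = 500, nfft = 256)
  expect_equal(gc2@gc[1, 2, ], g@gc[1, 2, ], tolerance = 1e-8)
})

test_that("chain mediation: pairwise influence vanishes under conditioning", {
  v <- varSpec(1:3, chainVar())
  pw <- analyticVarGC(v, fs = 250, nfft = 128, type = "pairwise")
  cd <- analyticVarGC(v, fs = 250, nfft = 128, type = "conditional")
  expect_gt(max(pw@gc[1, 3, ]), 0.01)
  expect_lt(max(cd@gc[1, 3, ]), 1e-6)
  # the direct links survive conditioning
  expect_gt(max(cd@gc[1, 2, ]), 0.01)
  expect_gt(max(cd@gc[2, 3, ]), 0.01)
})

test_that("unstable or singular VAR oracles are rejected", {
  unstable <- array(1.1, c(1, 1, 1))
  expect_error(analyticVarGC(list(coef = unstable, sigma = diag(1)),
                             fs = 100), "unstable")
  expect_error(analyticVarGC(list(coef = coupledVar(),
                                  sigma = matrix(c(1, 1, 1, 1), 2)),
                             fs = 100), "singular")
})

test_that("simulated coupled pair shows asymmetric estimated GC everywhere", {
  ep <- varEpochs(coupledVar(0.5), nTrials = 60, nSamples = 250, fs = 250,
                  seed = 5)
  csd <- estimateCSD(ep, window = c(0, 0.99), nTapers = 7)
  est <- gcSpectra(csd, freqRange = c(0, 125))
  expect_true(all(est@gc[1, 2, ] > est@gc[2, 1, ]))
})
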