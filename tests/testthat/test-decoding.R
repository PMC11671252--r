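gauss2 <- function(n, d, p = 3, seed = 1) {
  withr_seed <- seed; set.seed(withr_seed)
  x <- rbind(matrix(rnorm(n / 2 * p, 0), n / 2),
             matrix(rnorm(n / 2 * p, d), n / 2))
  list(x = x, y = factor(rep(c("a", "b"), each = n / 2)))
}

test_that("well-separated classes are decoded perfectly", {
  g <- gauss2(100, 6)
  res <- decodePoint(g$x, g$y, seed = 1)
  expect_equal(res$accuracy, 1)
  expect_length(res$fold, 5)
})

test_that("decoding is deterministic given the fold seed", {
  g <- gauss2(60, 0.8)
  a <- decodePoint(g$x, g$y, seed = 7)
  b <- decodePoint(g$x, g$y, seed = 7)
  expect_identical(a, b)
})

test_that("permuted labels decode at chance on average", {
  g <- gauss2(60, 2, seed = 3)
  set.seed(11)
  accs <- replicate(60, {
    decodePoint(g$x, sample(g$y), seed = 1)$accuracy
  })
  se <- sd(accs) / sqrt(length(accs))
  expect_lt(abs(mean(accs) - 0.5), 2 * se + 0.02)
})

test_that("degenerate feature inputs are rejected", {
  x <- matrix(rnorm(20), 10)
  expect_error(decodePoint(x, rep("a", 10)), "both classes")
  expect_error(decodePoint(x, c(rep("a", 9), "b")), "2 trials per class")
  xn <- x; xn[1, 1] <- NA
  expect_error(decodePoint(xn, rep(c("a", "b"), 5)), "missing")
  expect_error(decodePoint(x, rep(c("a", "b"), 5), nFolds = 1), "at least 2")
})

test_that("accuracy never decreases along an effect-size ladder", {
  accs <- vapply(c(0, 0.5, 1, 2, 4), function(d) {
    g <- gauss2(80, d, seed = 5)
    decodePoint(g$x, g$y, seed = 2)$accuracy
  }, numeric(1))
  expect_true(all(diff(accs) >= -0.02))
  expect_gt(accs[5], 0.95)
})

test_that("the bootstrap separates signal from null", {
  g <- gauss2(80, 5, seed = 2)
  bs <- bootstrapSignificance(g$x, g$y, nBoot = 200, seed = 3)
  expect_lt(bs$p, 0.01)
  expect_gt(bs$ci[1], 0.5)
  expect_true(bs$ci[1] <= bs$median && bs$median <= bs$ci[2])
  g0 <- gauss2(80, 0, seed = 4)
  bs0 <- bootstrapSignificance(g0$x, g0$y, nBoot = 200, seed = 5)
  expect_gt(bs0$p, 0.05)
  expect_warning(bootstrapSignificance(g$x, g$y, nBoot = 1, seed = 1),
                 "CI")
})

test_that("the time-frequency map has the decomposition's shape", {
  ep <- effectSession(nTrials = 24, channels = 1:2, band = c(30, 60),
                      window = c(0.1, 0.5), power = c(animate = 8, inanimate = 1),
                      amplitude = 2, fs = 250, epochWindow = c(-0.2, 0.8),
                      seed = 12)
  tfr <- multitaperTFR(ep, 0.2, 0.2, 3, 2, c(5, 100))
  map <- decodeTimeFreqMap(tfr, trialLabels(ep), seed = 1)
  expect_equal(dim(map$accuracy), c(length(tfr@freqs), length(tfr@times)))
  inBand <- map$freqs >= 30 & map$freqs <= 60
  inWin <- map$times > 0.1 & map$times < 0.5
  expect_gt(mean(map$accuracy[inBand, inWin]),
            mean(map$accuracy[!inBand, ]) + 0.1)
})

test_that("a planted band effect dominates band decoding in its window", {
  # the 0.5 s window at time-bandwidth 4 smooths over +/- 8 Hz, so the
  # planted band must be wide relative to that smearing: low gamma
  ep <- effectSession(nTrials = 40, channels = 1:4, band = c(35, 65),
                      window = c(0.2, 1.4), power = c(animate = 10, inanimate = 1),
                      amplitude = 2, fs = 250, epochWindow = c(-0.7, 1.8),
                      seed = 13)
  bd <- bandDecoding(ep, windows = list(effect = c(0.25, 1.35)),
                     freqRange = c(1.5, 100), nBoot = 0, seed = 1)
  expect_equal(bd$band[which.max(bd$accuracy)], "lowGamma")
})

test_that("band accuracies on null data stay near chance with covering CIs", {
  ep <- noiseSession(nTrials = 30, fs = 250, window = c(-0.7, 1.8),
                     grid = makeGrid(2, 2, arrayId = "x"), seed = 14)
  bd <- bandDecoding(ep, windows = list(w = c(0.25, 1.35)),
                     freqRange = c(1.5, 100), nBoot = 120, seed = 2)
  expect_true(all(bd$ciLow <= 0.5 + 1e-9 & bd$ciHigh >= 0.5 - 1e-9))
  expect_true(all(abs(bd$accuracy - 0.5) < 0.2))
})

test_that("the FDR step-up rule matches a brute-force oracle", {
  stepUp <- function(p, q) {
    # direct implementation of the step-up rule on sorted p-values
    m <- length(p)
    o <- order(p)
    k <- which(p[o] <= q * seq_len(m) / m)
    sig <- logical(m)
    if (length(k)) sig[o[seq_len(max(k))]] <- TRUE
    sig
  }
  expect_equal(fdrBH(c(0.01, 0.02, 0.03, 0.5))$significant,
               c(TRUE, TRUE, TRUE, FALSE))
  expect_true(all(fdrBH(rep(0.001, 100))$significant))
  expect_false(any(fdrBH(rep(1, 20))$significant))
  expect_length(fdrBH(numeric(0))$padj, 0)
  set.seed(8)
  for (i in 1:20) {
    p <- runif(sample(3:40, 1))^sample(1:3, 1)
    expect_equal(fdrBH(p, 0.05)$significant, stepUp(p, 0.05))
  }
})
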