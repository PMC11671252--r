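test_that("cross-spectra separate independent, identical and coupled sites", {
  ep <- noiseSession(nTrials = 50, fs = 250, window = c(-0.1, 1.1),
                     grid = makeGrid(1, 2, arrayId = "x"), seed = 41)
  csd <- estimateCSD(ep, window = c(0, 1), nTapers = 7)
  coh <- Mod(csd@csd[1, 2, ])^2 /
    (Re(csd@csd[1, 1, ]) * Re(csd@csd[2, 2, ]))
  expect_lt(mean(coh), 0.05)              # independent white noise
  ep2 <- ep
  ep2@data[, 2, ] <- ep2@data[, 1, ]
  csd2 <- estimateCSD(ep2, window = c(0, 1), nTapers = 7)
  coh2 <- Mod(csd2@csd[1, 2, ])^2 /
    (Re(csd2@csd[1, 1, ]) * Re(csd2@csd[2, 2, ]))
  expect_gt(min(coh2), 0.999)             # identical signals
})

test_that("the estimated CSD converges to the analytic VAR spectrum", {
  A <- coupledVar(0.5)
  fs <- 250; L <- 256
  ep <- varEpochs(A, nTrials = 400, nSamples = L, fs = fs, seed = 42)
  csd <- estimateCSD(ep, window = c(0, (L - 1) / fs), nTapers = 5, nfft = 256)
  nf1 <- length(csd@freqs)
  S <- array(0i, c(2, 2, nf1))
  for (k in seq_len(nf1)) {
    Ak <- diag(2) - A[, , 1] * exp(-2i * pi * csd@freqs[k] / fs)
    Hk <- solve(Ak)
    S[, , k] <- Hk %*% Conj(t(Hk))
  }
  # compare away from the edge bins, where tapering bias concentrates
  mid <- 5:(nf1 - 4)
  relerr <- max(Mod(csd@csd[, , mid] - S[, , mid])) / max(Mod(S))
  expect_lt(relerr, 0.1)
})

test_that("factorization reconstructs the spectrum and the innovations", {
  # identity spectrum factors trivially
  nf1 <- 65
  Sid <- array(0i, c(2, 2, nf1))
  for (k in seq_len(nf1)) Sid[, , k] <- diag(2)
  csd <- new("CrossSpectralDensity", csd = Sid,
             freqs = seq(0, 125, length.out = nf1), fs = 250,
             nTapers = 5L, nEpochs = 10L, window = c(0, 1),
             sites = c("a", "b"))
  f <- wilsonFactorize(csd)
  expect_equal(f@Sigma, diag(2), tolerance = 1e-8)
  for (k in c(1, 30, 65))
    expect_equal(f@H[, , k], diag(2) + 0i, tolerance = 1e-6)
  # a known VAR's analytic spectrum: Sigma and H recovered
  A <- coupledVar(0.5)
  nfft <- 128
  fgrid <- (0:64) * 250 / 128
  S <- array(0i, c(2, 2, 65)); Htrue <- array(0i, c(2, 2, 65))
  for (k in 1:65) {
    Hk <- solve(diag(2) - A[, , 1] * exp(-2i * pi * fgrid[k] / 250))
    Htrue[, , k] <- Hk
    S[, , k] <- Hk %*% Conj(t(Hk))
  }
  csdv <- new("CrossSpectralDensity", csd = S, freqs = fgrid, fs = 250,
              nTapers = 5L, nEpochs = 10L, window = c(0, 1),
              sites = c("a", "b"))
  fv <- wilsonFactorize(csdv)
  expect_lt(max(abs(fv@Sigma - diag(2))), 0.01)
  expect_lt(max(Mod(fv@H - Htrue)), 0.01)
  expect_lt(fv@residual, 1e-6)
})

test_that("conditional GC distinguishes direct from mediated influence", {
  A <- chainVar(0.5)
  ep <- varEpochs(A, nTrials = 120, nSamples = 250, fs = 250, seed = 43)
  csd <- estimateCSD(ep, window = c(0, 0.99), nTapers = 7)
  pw <- conditionalGC(csd, source = 1, target = 3, conditioning = character(0))
  cd <- conditionalGC(csd, source = 1, target = 3, conditioning = 2)
  expect_gt(max(pw$gc), 0.05)
  expect_lt(max(cd$gc), max(pw$gc) / 3)
  # direct coupling with an independent third site: conditioning is inert
  Ad <- array(0, c(3, 3, 1)); diag(Ad[, , 1]) <- 0.3; Ad[3, 1, 1] <- 0.5
  epd <- varEpochs(Ad, nTrials = 120, nSamples = 250, fs = 250, seed = 44)
  csdd <- estimateCSD(epd, window = c(0, 0.99), nTapers = 7)
  pwd <- conditionalGC(csdd, 1, 3, character(0))
  cdd <- conditionalGC(csdd, 1, 3, 2)
  expect_equal(max(cdd$gc), max(pwd$gc), tolerance = 0.15)
  expect_error(conditionalGC(csd, 1, 1), "must differ")
  expect_error(conditionalGC(csd, 1, 3, conditioning = 1), "exclude")
})

test_that("independent sites shrink toward zero GC as epochs grow", {
  maxima <- vapply(c(30, 120, 480), function(nt) {
    ep <- noiseSession(nTrials = nt, fs = 250, window = c(-0.1, 0.6),
                       grid = makeGrid(1, 2, arrayId = "x"), seed = 45)
    csd <- estimateCSD(ep, window = c(0, 0.5), nTapers = 5)
    max(gcSpectra(csd, freqRange = c(0, 125))@gc, na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(maxima) < 0))
  expect_lt(maxima[3], 0.02)
})

test_that("permutation thresholds flag only the coupled direction", {
  ep <- varEpochs(coupledVar(0.6), nTrials = 60, nSamples = 250, fs = 250,
                  seed = 46)
  # Bonferroni over 24 band-wise connections needs a permutation
  # p-value below 0.05/24, hence at least ~500 permutations
  pt <- permutationThreshold(ep, window = c(0, 0.99), nTapers = 7,
                             nPerm = 500, freqRange = c(0, 125), seed = 47)
  obsMax <- apply(pt@gc, c(1, 2), max)
  expect_gt(obsMax[1, 2], pt@threshold[1, 2])
  expect_lt(obsMax[2, 1], pt@threshold[2, 1])
  expect_lt(pt@padj[1, 2], 0.05)
  expect_equal(pt@padj[1, 2], min(1, pt@p[1, 2] * 24))
  expect_warning(
    permutationThreshold(ep, window = c(0, 0.99), nTapers = 7, nPerm = 20,
                         freqRange = c(0, 125), seed = 1),
    "nPerm")
})

test_that("GC spectra are invariant to a common-mode signal after bipolar derivation", {
  grid <- makeGrid(2, 2, arrayId = "x")
  ep <- simulateSession(synthConfig(nTrials = 40, fs = 250,
                                    epochWindow = c(-0.1, 1.1), grid = grid,
                                    var = varSpec(c(1, 2), coupledVar(0.5)),
                                    seed = 48))
  common <- sin(2 * pi * 11 * epochTimes(ep)) * 3
  epc <- ep
  for (ch in 1:4) epc@data[, ch, ] <- sweep(epc@data[, ch, ], 2, common, `+`)
  bp1 <- bipolarDerive(ep, c(3, 4), grid)
  bp2 <- bipolarDerive(epc, c(3, 4), grid)
  expect_equal(bp1@data, bp2@data, tolerance = 1e-10)
})

test_that("the band-wise directionality statistic follows its rules", {
  freqs <- seq(0, 50, by = 1)
  mk <- function(spec12, spec21, thr = c(0.05, 0.05)) {
    gc <- array(NA_real_, c(2, 2, length(freqs)))
    gc[1, 2, ] <- spec12; gc[2, 1, ] <- spec21
    new("GCSpectra", gc = gc, freqs = freqs, sites = c("A", "B"),
        threshold = matrix(c(NA, thr[2], thr[1], NA), 2, 2), p = matrix(numeric(0), 0, 0),
        padj = matrix(numeric(0), 0, 0), nPerm = 100L, diagnostics = list())
  }
  # identical spectra in both directions: zero asymmetry, no direction
  s <- 0.1 + 0.05 * exp(-(freqs - 20)^2 / 8)
  dg <- dgcByBand(mk(s, s))
  expect_true(all(dg$dgc[dg$rule == "tie"] == 0))
  expect_true(all(is.na(dg$from[dg$rule == "tie"])))
  # only one significant direction: dGC is that direction's band value
  lo <- rep(0.01, length(freqs))
  dg2 <- dgcByBand(mk(s, lo))
  beta <- dg2[dg2$band == "beta", ]
  expect_equal(beta$from, "A"); expect_equal(beta$to, "B")
  expect_equal(beta$rule, "single")
  sm <- ecogflow:::smooth3(s)[freqs >= 14 & freqs <= 30]
  pk <- ecogflow:::bandPeak(sm)
  expect_equal(beta$dgc, sm[pk])
  # a constructed peak asymmetry: dGC equals the hand-computed difference
  s2 <- 0.08 + 0.03 * exp(-(freqs - 20)^2 / 8)
  dg3 <- dgcByBand(mk(s, s2, thr = c(0.05, 0.05)))
  beta3 <- dg3[dg3$band == "beta", ]
  smA <- ecogflow:::smooth3(s)[freqs >= 14 & freqs <= 30]
  smB <- ecogflow:::smooth3(s2)[freqs >= 14 & freqs <= 30]
  expect_equal(beta3$dgc, smA[pk] - smB[pk])
  expect_equal(beta3$rule, "peak")
  # neither direction significant: marked none
  dg4 <- dgcByBand(mk(lo, lo, thr = c(0.5, 0.5)))
  expect_true(all(dg4$rule == "none"))
  expect_true(all(is.na(dg4$dgc)))
})

test_that("site-pair pooling matches the 4-site, 3-subregion design", {
  pp <- poolPairs(c("ITC", "STSv", "STSf", "STSf"))
  expect_equal(pp$nInter, 5)
  expect_equal(pp$nIntra, 1)
  expect_error(poolPairs(rep("ITC", 4)), "3 subregions")
  expect_error(poolPairs(c("a", "b", "c", "d")), "3 subregions")
  # pooled spectra: 6 directed subregion-level connections, averaging
  # the two site pairs that share the doubled subregion
  nf <- 7
  gc <- array(NA_real_, c(4, 4, nf))
  for (i in 1:4) for (j in 1:4) if (i != j) gc[i, j, ] <- i * 10 + j
  g <- new("GCSpectra", gc = gc, freqs = 1:nf, sites = as.character(1:4),
           threshold = matrix(1, 4, 4), p = matrix(numeric(0), 0, 0),
           padj = matrix(numeric(0), 0, 0), nPerm = 10L,
           diagnostics = list())
  pl <- poolPairs(c("ITC", "STSv", "STSf", "STSf"), g)
  pooled <- pl$pooled
  expect_equal(sum(!is.na(pooled@gc[, , 1])), 6)
  i <- which(pooled@sites == "ITC"); s <- which(pooled@sites == "STSf")
  expect_equal(pooled@gc[i, s, 1], mean(c(13, 14)))   # sites 3 and 4 pooled
  expect_equal(pooled@gc[s, i, 1], mean(c(31, 41)))
})
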