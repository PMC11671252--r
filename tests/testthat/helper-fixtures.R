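# Shared fixture builders. Everything is generated in code; sizes are
# kept small so the default run stays fast.

# Plain white-noise session on a small grid.
noiseSession <- function(nTrials = 20, fs = 250, window = c(-0.2, 0.6),
                         grid = makeGrid(2, 2, arrayId = "x"), seed = 1) {
  simulateSession(synthConfig(nTrials = nTrials, fs = fs,
                              epochWindow = window, grid = grid,
                              seed = seed))
}

# Session with a planted band-limited category effect.
effectSession <- function(nTrials = 40, channels = c(1, 2),
                          band = c(20, 40), window = c(0.1, 0.5),
                          power = c(animate = 4, inanimate = 1),
                          amplitude = 1.5, evoked = 0, fs = 250,
                          epochWindow = c(-0.2, 0.8),
                          grid = makeGrid(2, 2, arrayId = "x"), seed = 2) {
  eff <- effectSpec(channels, band, window, power, amplitude,
                    evoked = evoked)
  simulateSession(synthConfig(nTrials = nTrials, fs = fs,
                              epochWindow = epochWindow, grid = grid,
                              effects = list(eff), seed = seed))
}

# Unidirectional lag-1 coupling 1 -> 2, the canonical coupled pair.
coupledVar <- function(coupling = 0.5) {
  A <- array(0, c(2, 2, 1))
  A[1, 1, 1] <- 0.5; A[2, 2, 1] <- 0.2; A[2, 1, 1] <- coupling
  A
}

# Chain 1 -> 2 -> 3 with no direct 1 -> 3 coefficient.
chainVar <- function(coupling = 0.5) {
  A <- array(0, c(3, 3, 1))
  diag(A[, , 1]) <- 0.3
  A[2, 1, 1] <- coupling
  A[3, 2, 1] <- coupling
  A
}

# TrialEpochs wrapper around an externally built data array.
epochsFromArray <- function(dat, fs, t0 = 0, labels = NULL, grid = NULL) {
  nt <- dim(dat)[1]
  if (is.null(labels))
    labels <- factor(rep_len(c("animate", "inanimate"), nt),
                     levels = c("animate", "inanimate"))
  new("TrialEpochs", data = dat, fs = fs,
      times = t0 + (seq_len(dim(dat)[3]) - 1) / fs,
      labels = labels, grid = grid, provenance = "fixture")
}

# Continuous VAR realization cut into epochs (m channels).
varEpochs <- function(coef, nTrials, nSamples, fs, sigma = NULL,
                      seed = 1, t0 = 0) {
  m <- dim(coef)[1]
  x <- simulateVAR(coef, sigma, n = nTrials * nSamples, seed = seed)
  epochsFromArray(aperm(array(x, c(m, nSamples, nTrials)), c(3, 1, 2)),
                  fs = fs, t0 = t0)
}
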