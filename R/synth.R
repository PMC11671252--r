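#' Describe a category-dependent band-limited power effect
#'
#' An effect injects band-limited noise into a set of channels inside a
#' time window, with the injected power scaled per category. The
#' carrier is white noise restricted to the band in the frequency
#' domain; its amplitude follows a raised-cosine onset/offset envelope
#' so the spectral contrast is smooth and parameterizable.
#'
#' @param channels channel ids receiving the effect.
#' @param band numeric(2), frequency band in Hz.
#' @param window numeric(2), onset/offset in seconds.
#' @param power named numeric, per-category power scaling of the
#'   injected component (e.g. `c(animate = 1.5, inanimate = 1)`).
#' @param amplitude baseline amplitude (standard deviation) of the
#'   injected component at power scale 1.
#' @param ramp raised-cosine ramp duration in seconds (default 10 ms).
#' @param evoked amplitude of an additional deterministic carrier at
#'   the band centre frequency (identical across trials of a category,
#'   scaled like the stochastic part). 0 (default) models a pure
#'   induced-power effect; a positive value adds a phase-locked evoked
#'   component so that category information is also present in the raw
#'   voltage waveform.
#' @param shared when TRUE, one band-noise realization per trial
#'   drives all effect channels (a genuine subnetwork source spanning
#'   the channel set); when FALSE (default) every channel receives an
#'   independent realization.
#' @return a list of class `"effectSpec"`.
#' @export
effectSpec <- function(channels, band, window,
                       power = c(animate = 1.5, inanimate = 1),
                       amplitude = 1, ramp = 0.010, evoked = 0,
                       shared = FALSE) {
  stopifnot(length(band) == 2L, band[1] < band[2], band[1] >= 0,
            length(window) == 2L, window[1] < window[2],
            amplitude > 0, ramp >= 0, evoked >= 0)
  structure(list(channels = as.integer(channels), band = band,
                 window = window, power = power, amplitude = amplitude,
                 ramp = ramp, evoked = evoked, shared = isTRUE(shared)),
            class = "effectSpec")
}

#' Describe an embedded multivariate autoregressive subnetwork
#'
#' @param channels channel ids carrying the MVAR process (length m).
#' @param coef m x m x p array of VAR coefficient matrices;
#'   `coef[i, j, k]` is the influence of channel j at lag k on channel i.
#' @param sigma m x m innovation covariance (default identity).
#' @param amplitude scaling applied to the process before it is added
#'   to the channel noise.
#' @param labelGain optional named numeric multiplying the off-diagonal
#'   (coupling) coefficients per category, to plant category information
#'   in connectivity; NULL (off) by default.
#' @return a list of class `"varSpec"`.
#' @export
varSpec <- function(channels, coef, sigma = NULL, amplitude = 1,
                    labelGain = NULL) {
  m <- length(channels)
  if (length(dim(coef)) == 2L) coef <- array(coef, c(dim(coef), 1L))
  stopifnot(length(dim(coef)) == 3L, dim(coef)[1] == m, dim(coef)[2] == m)
  if (is.null(sigma)) sigma <- diag(m)
  stopifnot(all(dim(sigma) == m))
  if (min(eigen(sigma, symmetric = TRUE, only.values = TRUE)$values) <= 0)
    stop("innovation covariance must be positive definite")
  structure(list(channels = as.integer(channels), coef = coef,
                 sigma = sigma, amplitude = amplitude,
                 labelGain = labelGain),
            class = "varSpec")
}

# Spectral radius of the VAR companion matrix.
varSpectralRadius <- function(coef) {
  m <- dim(coef)[1]; p <- dim(coef)[3]
  comp <- matrix(0, m * p, m * p)
  for (k in seq_len(p)) comp[1:m, (k - 1) * m + 1:m] <- coef[, , k]
  if (p > 1) comp[(m + 1):(m * p), 1:(m * (p - 1))] <- diag(m * (p - 1))
  max(Mod(eigen(comp, only.values = TRUE)$values))
}

#' Simulate a stationary VAR realization
#'
#' @param coef m x m x p coefficient array (see [varSpec()]).
#' @param sigma innovation covariance.
#' @param n number of samples to return.
#' @param burn burn-in samples discarded at the start.
#' @param seed optional RNG seed.
#' @return m x n matrix, one row per channel.
#' @export
simulateVAR <- function(coef, sigma = NULL, n, burn = 200, seed = NULL) {
  if (length(dim(coef)) == 2L) coef <- array(coef, c(dim(coef), 1L))
  m <- dim(coef)[1]; p <- dim(coef)[3]
  if (is.null(sigma)) sigma <- diag(m)
  rho <- varSpectralRadius(coef)
  if (rho >= 1)
    stop(sprintf("unstable VAR: companion spectral radius %.3f >= 1", rho))
  withSeed(seed, {
    L <- chol(sigma)
    e <- matrix(rnorm((n + burn) * m), n + burn, m) %*% L
    x <- matrix(0, n + burn, m)
    A <- lapply(seq_len(p), function(k) t(coef[, , k]))
    for (t in seq(p + 1, n + burn)) {
      acc <- e[t, ]
      for (k in seq_len(p)) acc <- acc + x[t - k, ] %*% A[[k]]
      x[t, ] <- acc
    }
    t(x[(burn + 1):(burn + n), , drop = FALSE])
  })
}

#' Configuration for a synthetic recording session
#'
#' Bundles everything [simulateSession()] needs: trial count, sampling,
#' epoch window, label balance, planted band-limited category effects,
#' an optional embedded MVAR subnetwork, the background noise floor and
#' optional line-noise contamination. Defaults mirror the emulated
#' recording setup at desk scale: a 192-channel two-array grid, 200
#' trials, epochs from -0.7 s to 4 s at 500 Hz, balanced labels.
#'
#' @param nTrials number of trials.
#' @param fs sampling rate in Hz.
#' @param epochWindow numeric(2) epoch span in seconds around onset.
#' @param labelBalance proportion of "animate" trials.
#' @param grid an [ElectrodeGrid-class] (default [defaultSessionGrid()]).
#' @param effects list of [effectSpec()] objects.
#' @param var a [varSpec()] or NULL.
#' @param noiseFloor variance of the background Gaussian noise.
#' @param lineNoise optional `list(freq = , amplitude = )`.
#' @param seed integer RNG seed (required for reproducibility).
#' @return a list of class `"synthConfig"`.
#' @export
synthConfig <- function(nTrials = 200, fs = 500, epochWindow = c(-0.7, 4),
                        labelBalance = 0.5, grid = defaultSessionGrid(),
                        effects = list(), var = NULL, noiseFloor = 1,
                        lineNoise = NULL, seed = 1L) {
  stopifnot(nTrials >= 2, fs > 0, epochWindow[1] < epochWindow[2],
            labelBalance > 0, labelBalance < 1, noiseFloor > 0)
  if (inherits(effects, "effectSpec")) effects <- list(effects)
  for (ef in effects) {
    stopifnot(inherits(ef, "effectSpec"))
    if (ef$band[2] > fs / 2)
      stop(sprintf("effect band upper edge %.1f Hz exceeds Nyquist %.1f Hz",
                   ef$band[2], fs / 2))
    if (!all(ef$channels %in% channelTable(grid)$channel))
      stop("effect channels must be a subset of the grid channels")
  }
  if (!is.null(var)) {
    stopifnot(inherits(var, "varSpec"))
    if (!all(var$channels %in% channelTable(grid)$channel))
      stop("VAR channels must be a subset of the grid channels")
    rho <- varSpectralRadius(var$coef)
    if (rho >= 1)
      stop(sprintf("unstable VAR: companion spectral radius %.3f >= 1", rho))
    if (!is.null(var$labelGain)) {
      for (g in var$labelGain) {
        scaled <- var$coef
        for (k in seq_len(dim(scaled)[3])) {
          off <- scaled[, , k]; diag(off) <- 0
          scaled[, , k] <- g * off + diag(diag(var$coef[, , k]))
        }
        rho <- varSpectralRadius(scaled)
        if (rho >= 1)
          stop(sprintf("label-scaled VAR unstable (gain %.2f, radius %.3f)", g, rho))
      }
    }
  }
  structure(list(nTrials = as.integer(nTrials), fs = fs,
                 epochWindow = epochWindow, labelBalance = labelBalance,
                 grid = grid, effects = effects, var = var,
                 noiseFloor = noiseFloor, lineNoise = lineNoise,
                 seed = as.integer(seed)),
            class = "synthConfig")
}

# Unit-variance white noise restricted to `band` via its Fourier mask.
bandNoise <- function(n, fs, band) {
  X <- fft(rnorm(n))
  f <- (0:(n - 1)) * fs / n
  f <- pmin(f, fs - f)
  X[f < band[1] | f > band[2]] <- 0
  y <- Re(fft(X, inverse = TRUE)) / n
  s <- sd(y)
  if (s < .Machine$double.eps) stop("band too narrow for epoch length")
  y / s
}

# Raised-cosine onset/offset envelope on the epoch time axis.
effectEnvelope <- function(times, window, ramp) {
  env <- numeric(length(times))
  inside <- times >= window[1] & times <= window[2]
  env[inside] <- 1
  if (ramp > 0) {
    up <- inside & times < window[1] + ramp
    env[up] <- 0.5 * (1 - cos(pi * (times[up] - window[1]) / ramp))
    dn <- inside & times > window[2] - ramp
    env[dn] <- 0.5 * (1 - cos(pi * (window[2] - times[dn]) / ramp))
  }
  env
}

#' Generate a synthetic trial-epoched session with known ground truth
#'
#' All channels carry independent Gaussian background noise at the
#' configured noise floor. Channels listed in the MVAR spec additionally
#' carry a per-trial realization of the (stable) MVAR process, giving
#' known frequency-resolved directed couplings. Channels listed in
#' effect specs additionally carry band-limited noise whose power is
#' scaled per trial category inside the effect window, giving known
#' decodable category contrasts. Identical configurations (including
#' the seed) produce bit-identical epochs.
#'
#' @param config a [synthConfig()].
#' @return a [TrialEpochs-class] with labels "animate"/"inanimate".
#' @export
simulateSession <- function(config) {
  stopifnot(inherits(config, "synthConfig"))
  fs <- config$fs
  times <- seq(config$epochWindow[1], config$epochWindow[2], by = 1 / fs)
  ns <- length(times)
  nch <- nChannels(config$grid)
  nt <- config$nTrials
  withSeed(config$seed, {
    nAnim <- round(nt * config$labelBalance)
    labels <- factor(sample(rep(c("animate", "inanimate"),
                                c(nAnim, nt - nAnim))),
                     levels = c("animate", "inanimate"))
    dat <- array(rnorm(nt * nch * ns, sd = sqrt(config$noiseFloor)),
                 dim = c(nt, nch, ns))
    if (!is.null(config$lineNoise)) {
      ln <- config$lineNoise
      for (tr in seq_len(nt)) {
        wave <- ln$amplitude * sin(2 * pi * ln$freq * times + runif(1, 0, 2 * pi))
        dat[tr, , ] <- sweep(dat[tr, , , drop = FALSE][1, , ], 2, wave, `+`)
      }
    }
    if (!is.null(config$var)) {
      v <- config$var
      for (tr in seq_len(nt)) {
        coef <- v$coef
        if (!is.null(v$labelGain)) {
          g <- v$labelGain[[as.character(labels[tr])]]
          if (!is.null(g) && !is.na(g)) {
            for (k in seq_len(dim(coef)[3])) {
              off <- coef[, , k]; diag(off) <- 0
              coef[, , k] <- g * off + diag(diag(v$coef[, , k]))
            }
          }
        }
        x <- simulateVAR(coef, v$sigma, n = ns, burn = 200)
        dat[tr, v$channels, ] <- dat[tr, v$channels, ] + v$amplitude * x
      }
    }
    for (ef in config$effects) {
      env <- effectEnvelope(times, ef$window, ef$ramp)
      carrier <- if (ef$evoked > 0)
        sin(2 * pi * mean(ef$band) * (times - ef$window[1])) else NULL
      for (tr in seq_len(nt)) {
        p <- ef$power[[as.character(labels[tr])]]
        if (is.null(p) || is.na(p)) p <- 1
        amp <- ef$amplitude * sqrt(p)
        common <- if (isTRUE(ef$shared)) bandNoise(ns, fs, ef$band) else NULL
        for (chn in ef$channels) {
          carrierNoise <- common %||% bandNoise(ns, fs, ef$band)
          dat[tr, chn, ] <- dat[tr, chn, ] + amp * env * carrierNoise
          if (!is.null(carrier))
            dat[tr, chn, ] <- dat[tr, chn, ] + ef$evoked * sqrt(p) * env * carrier
        }
      }
    }
    new("TrialEpochs", data = dat, fs = fs, times = times, labels = labels,
        grid = config$grid,
        provenance = sprintf(
          "simulateSession(seed=%d, nTrials=%d, %d effects%s)",
          config$seed, nt, length(config$effects),
          if (is.null(config$var)) "" else ", MVAR subnetwork"))
  })
}

#' Closed-form spectral Granger causality of a known VAR process
#'
#' Computes frequency-resolved directed influence for a stable VAR with
#' known coefficients and innovation covariance, without estimating
#' anything from data. The full-model transfer function
#' H(f) = (I - sum_k A_k e^{-2 pi i f k / fs})^{-1} and the innovation
#' covariance are evaluated analytically; for `type = "conditional"`
#' the reduced model (all channels except the source) is obtained by
#' minimum-phase factorization of the exact reduced spectral matrix,
#' and for `type = "pairwise"` in a two-channel VAR the classical
#' bivariate formula applies in closed form with no factorization at
#' all.
#'
#' @param var a [varSpec()] or a `list(coef = , sigma = )`.
#' @param freqs optional frequencies (Hz) at which to report GC; by
#'   default the internal uniform grid up to the Nyquist frequency.
#' @param fs sampling rate of the process (Hz).
#' @param nfft internal frequency grid size (full circle).
#' @param type "conditional" (on all remaining channels) or "pairwise"
#'   (marginal two-channel influence).
#' @return a [GCSpectra-class] with `gc[i, j, ]` = influence i -> j.
#' @export
analyticVarGC <- function(var, freqs = NULL, fs = 500, nfft = 512,
                          type = c("conditional", "pairwise")) {
  type <- match.arg(type)
  coef <- var$coef
  if (length(dim(coef)) == 2L) coef <- array(coef, c(dim(coef), 1L))
  sigma <- var$sigma %||% diag(dim(coef)[1])
  m <- dim(coef)[1]; p <- dim(coef)[3]
  rho <- varSpectralRadius(coef)
  if (rho >= 1)
    stop(sprintf("unstable VAR: companion spectral radius %.3f >= 1", rho))
  if (min(eigen(sigma, symmetric = TRUE, only.values = TRUE)$values) <=
      1e-12 * max(abs(sigma)))
    stop("singular innovation covariance")
  nf1 <- nfft %/% 2 + 1L
  fgrid <- (0:(nfft %/% 2)) * fs / nfft
  H <- array(0i, c(m, m, nf1))
  S <- array(0i, c(m, m, nf1))
  for (k in seq_len(nf1)) {
    A <- diag(m) + 0i
    for (l in seq_len(p))
      A <- A - coef[, , l] * exp(-2i * pi * fgrid[k] * l / fs)
    Hk <- solve(A)
    H[, , k] <- Hk
    S[, , k] <- Hk %*% sigma %*% Conj(t(Hk))
  }
  gc <- array(NA_real_, c(m, m, nf1))
  if (type == "pairwise" && m == 2) {
    for (i in 1:2) {
      j <- 3 - i
      Syy <- Re(S[j, j, ])
      sxx <- sigma[i, i]
      syyx <- sigma[j, j] - sigma[j, i]^2 / sxx
      intrinsic <- Mod(H[j, j, ])^2 * syyx
      gc[i, j, ] <- pmax(log(Syy / pmax(intrinsic, Syy * 1e-12)), 0)
    }
  } else if (type == "pairwise") {
    for (i in seq_len(m)) for (j in seq_len(m)) {
      if (i == j) next
      sub <- S[c(i, j), c(i, j), , drop = FALSE]
      fullF <- wilsonCore(sub, fs = fs)
      redF <- wilsonCore(sub[2, 2, , drop = FALSE], fs = fs)
      gc[i, j, ] <- gcFromFactorizations(fullF$H, fullF$Sigma, redF$H, redF$Sigma)
    }
  } else {
    for (i in seq_len(m)) {
      others <- setdiff(seq_len(m), i)
      redF <- wilsonCore(S[others, others, , drop = FALSE], fs = fs)
      for (j in others) {
        ordFull <- c(i, j, setdiff(others, j))
        ordRed <- match(c(j, setdiff(others, j)), others)
        gc[i, j, ] <- gcFromFactorizations(
          H[ordFull, ordFull, , drop = FALSE],
          sigma[ordFull, ordFull, drop = FALSE],
          redF$H[ordRed, ordRed, , drop = FALSE],
          redF$Sigma[ordRed, ordRed, drop = FALSE])
      }
    }
  }
  if (!is.null(freqs)) {
    out <- array(NA_real_, c(m, m, length(freqs)))
    for (i in seq_len(m)) for (j in seq_len(m)) {
      if (i == j) next
      out[i, j, ] <- approx(fgrid, gc[i, j, ], xout = freqs, rule = 2)$y
    }
    gc <- out; fgrid <- freqs
  }
  sites <- as.character(var$channels %||% seq_len(m))
  new("GCSpectra", gc = gc, freqs = fgrid, sites = sites,
      threshold = matrix(numeric(0), 0, 0), p = matrix(numeric(0), 0, 0),
      padj = matrix(numeric(0), 0, 0), nPerm = 0L,
      diagnostics = list(type = type, analytic = TRUE))
}

#' @importFrom stats approx
NULL
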