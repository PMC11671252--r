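#' Discrete prolate spheroidal (Slepian) tapers
#'
#' Computes the first `k` DPSS tapers of length `n` at time-bandwidth
#' product `nw` as eigenvectors of the standard symmetric tridiagonal
#' formulation, ordered by decreasing spectral concentration and
#' normalized to unit energy.
#'
#' @param n taper length in samples.
#' @param nw time-bandwidth product (e.g. 4).
#' @param k number of tapers (must satisfy k <= 2 nw - 1).
#' @return n x k matrix, one taper per column.
#' @export
dpssTapers <- function(n, nw = 4, k = 2 * nw - 1) {
  stopifnot(n >= 2, nw > 0, k >= 1)
  if (k > 2 * nw - 1)
    stop("k must satisfy k <= 2 * nw - 1 for well-concentrated tapers")
  if (k > n) stop("cannot compute more tapers than samples")
  W <- nw / n
  tt <- 0:(n - 1)
  A <- matrix(0, n, n)
  diag(A) <- ((n - 1 - 2 * tt) / 2)^2 * cos(2 * pi * W)
  off <- (1:(n - 1)) * (n - (1:(n - 1))) / 2
  A[cbind(1:(n - 1), 2:n)] <- off
  A[cbind(2:n, 1:(n - 1))] <- off
  v <- eigen(A, symmetric = TRUE)$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    v[, j] <- v[, j] / sqrt(sum(v[, j]^2))
    if (v[which.max(abs(v[, j])), j] < 0) v[, j] <- -v[, j]
  }
  v
}

#' Moving-window multitaper time-frequency decomposition
#'
#' Slides a window across the epoch and estimates power per trial,
#' channel, frequency and window position by averaging DPSS-tapered
#' periodograms over tapers. Window time stamps are the window-centre
#' sample; the first window begins at the epoch start. The FFT length
#' is the next power of two of the window sample count by default
#' (`fftMode = "exact"` uses the window length itself).
#'
#' @param epochs a [TrialEpochs-class].
#' @param windowS window length in seconds.
#' @param stepS step between window starts in seconds.
#' @param nTapers number of Slepian tapers.
#' @param timeBandwidth DPSS time-bandwidth product.
#' @param freqRange numeric(2), retained frequency range in Hz
#'   (ignored when `freqList` is given).
#' @param freqList optional specific frequencies (Hz); each is mapped
#'   to the nearest FFT bin.
#' @param fftMode "nextpow2" or "exact".
#' @param channels optional channel subset.
#' @return a raw [SpectralPerturbation-class]
#'   (trials x channels x freqs x times).
#' @export
multitaperTFR <- function(epochs, windowS = 0.4, stepS = 0.05,
                          nTapers = 6L, timeBandwidth = 4,
                          freqRange = c(1.5, 150), freqList = NULL,
                          fftMode = c("nextpow2", "exact"),
                          channels = NULL) {
  stopifnot(is(epochs, "TrialEpochs"))
  fftMode <- match.arg(fftMode)
  fs <- epochs@fs
  dat <- epochs@data
  if (!is.null(channels)) dat <- dat[, channels, , drop = FALSE]
  nt <- dim(dat)[1]; nch <- dim(dat)[2]; ns <- dim(dat)[3]
  L <- round(windowS * fs)
  step <- max(1L, round(stepS * fs))
  if (L > ns) stop("window does not fit in the epoch")
  if (nTapers > 2 * timeBandwidth - 1)
    stop("nTapers must be <= 2 * timeBandwidth - 1")
  nfft <- if (fftMode == "nextpow2") nextPow2(L) else as.integer(L)
  binFreqs <- (0:(nfft %/% 2)) * fs / nfft
  if (is.null(freqList)) {
    if (freqRange[2] > fs / 2) stop("requested frequency exceeds Nyquist")
    sel <- which(binFreqs >= freqRange[1] & binFreqs <= freqRange[2])
  } else {
    if (max(freqList) > fs / 2) stop("requested frequency exceeds Nyquist")
    sel <- unique(vapply(freqList, function(f) which.min(abs(binFreqs - f)),
                         integer(1)))
    sel <- sort(sel)
  }
  if (!length(sel)) stop("no FFT bins inside the requested frequency range")
  starts <- seq(1L, ns - L + 1L, by = step)
  centers <- epochs@times[starts + L %/% 2]
  tapers <- dpssTapers(L, timeBandwidth, nTapers)
  power <- array(0, c(nt, nch, length(sel), length(starts)))
  nser <- nt * nch
  pad <- matrix(0, nfft, nser)
  for (w in seq_along(starts)) {
    idx <- starts[w]:(starts[w] + L - 1L)
    seg <- t(matrix(dat[, , idx], nser, L))   # L x (trials*channels)
    acc <- matrix(0, length(sel), nser)
    for (k in seq_len(nTapers)) {
      pad[] <- 0
      pad[seq_len(L), ] <- seg * tapers[, k]
      acc <- acc + Mod(mvfft(pad)[sel, , drop = FALSE])^2
    }
    power[, , , w] <- array(t(acc / (nTapers * fs)), c(nt, nch, length(sel)))
  }
  new("SpectralPerturbation", power = power, freqs = binFreqs[sel],
      times = centers,
      params = list(windowS = windowS, stepS = stepS, nTapers = nTapers,
                    timeBandwidth = timeBandwidth, nfft = nfft,
                    fftMode = fftMode,
                    freqRange = if (is.null(freqList)) freqRange else NULL,
                    freqList = freqList),
      normalized = FALSE, baselineWindow = numeric(0))
}

#' Single-trial baseline normalization to decibels (ERSP)
#'
#' Divides each trial's time-frequency power by that trial's mean
#' power over the pre-stimulus baseline window at the same frequency
#' and channel, averages the ratios over trials, and converts to dB
#' (10 log10).
#'
#' @param tfr a raw [SpectralPerturbation-class] with per-trial power.
#' @param baselineWindow numeric(2) baseline window in seconds
#'   (default -0.7 to 0 s).
#' @return a normalized [SpectralPerturbation-class]
#'   (channels x freqs x times, dB).
#' @export
baselineNormalize <- function(tfr, baselineWindow = c(-0.7, 0)) {
  stopifnot(is(tfr, "SpectralPerturbation"))
  if (tfr@normalized) stop("input is already normalized")
  if (length(dim(tfr@power)) != 4L)
    stop("per-trial (4-d) power is required for single-trial normalization")
  bidx <- timesInWindow(tfr@times, baselineWindow)
  if (!length(bidx)) stop("baseline window contains no time points")
  d <- dim(tfr@power)
  base <- apply(tfr@power[, , , bidx, drop = FALSE], c(1, 2, 3), mean)
  if (min(base) <= 0) {
    bad <- which(base <= 0, arr.ind = TRUE)[1, ]
    stop(sprintf("zero baseline power (trial %d, channel %d, frequency %.2f Hz)",
                 bad[1], bad[2], tfr@freqs[bad[3]]))
  }
  ratio <- tfr@power / as.vector(base)    # recycles over the time dim
  avg <- apply(ratio, c(2, 3, 4), mean)
  new("SpectralPerturbation", power = 10 * log10(avg), freqs = tfr@freqs,
      times = tfr@times, params = tfr@params, normalized = TRUE,
      baselineWindow = baselineWindow)
}

#' Canonical frequency-band definitions for band-wise decoding
#'
#' @return named list of Hz intervals: delta 2-4, theta 5-8, alpha
#'   9-13, beta 14-30, low gamma 31-70, high gamma 71-200.
#' @export
frequencyBands <- function() {
  list(delta = c(2, 4), theta = c(5, 8), alpha = c(9, 13), beta = c(14, 30),
       lowGamma = c(31, 70), highGamma = c(71, 200))
}
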