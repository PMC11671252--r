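# Frequency-resolved conditional Granger causality between selected
# sites: multitaper cross-spectra, Wilson minimum-phase factorization,
# Geweke conditional influence, permutation thresholds and the
# band-wise directionality statistic.

# Internal: factorize a one-sided CSD array (m x m x nf1, grid 0..fs/2)
# into transfer H (one-sided) and innovation covariance Sigma.
wilsonCore <- function(S1, fs, tol = 1e-9, maxit = 1000L) {
  d <- dim(S1)
  m <- d[1]; nf1 <- d[3]
  nfft <- 2L * (nf1 - 1L)
  full <- array(0i, c(m, m, nfft))
  full[, , seq_len(nf1)] <- S1
  if (nf1 > 2L) {
    for (k in 2:(nf1 - 1L)) full[, , nfft + 2L - k] <- t(S1[, , k])
  }
  res <- tryCatch(
    wilson_factor_cpp(full, tol, as.integer(maxit)),
    error = function(e) {
      ridge <- mean(Re(apply(S1, 3, function(x) sum(diag(x))))) / m * 1e-6
      for (k in seq_len(nfft)) full[, , k] <- full[, , k] + ridge * diag(m)
      r <- wilson_factor_cpp(full, tol, as.integer(maxit))
      r$ridged <- ridge
      r
    })
  A0 <- res$A0
  A0inv <- solve(A0)
  psi <- res$psi
  H <- array(0i, c(m, m, nf1))
  for (k in seq_len(nf1)) H[, , k] <- psi[, , k] %*% A0inv
  Sigma <- A0 %*% t(A0)
  # reconstruction residual over the one-sided grid
  rel <- 0
  sc <- max(Mod(S1))
  for (k in seq_len(nf1)) {
    rec <- H[, , k] %*% Sigma %*% Conj(t(H[, , k]))
    rel <- max(rel, max(Mod(rec - S1[, , k])) / sc)
  }
  list(H = H, Sigma = Sigma, iterations = as.integer(res$iterations),
       relerr = res$relerr, residual = rel,
       ridged = res$ridged %||% 0)
}

# Internal: Geweke conditional influence x -> y | z from a full model
# (H, Sigma; sites ordered x, y, z...) and the reduced-model
# factorization over (y, z...). Returns the nonnegative GC spectrum.
gcFromFactorizations <- function(H, Sigma, Hred, SigmaR) {
  m <- dim(H)[1]; nf <- dim(H)[3]
  Sxx <- Sigma[1, 1]
  wgt <- Sigma[2:m, 1] / Sxx
  SigRyy <- SigmaR[1, 1]
  out <- numeric(nf)
  for (k in seq_len(nf)) {
    Hk <- H[, , k]
    Qy <- if (m == 2L) Hk[2, ] / Hred[1, 1, k]
          else solve(Hred[, , k], Hk[2:m, , drop = FALSE])[1, ]
    qt <- Qy[1] + sum(Qy[2:m] * wgt)
    den <- SigRyy - Sxx * Mod(qt)^2
    out[k] <- log(SigRyy / max(den, SigRyy * 1e-12))
  }
  pmax(out, 0)
}

#' Multitaper cross-spectral density of selected sites
#'
#' Taper- and epoch-averaged cross-periodograms of the site signals
#' within an analysis window, on the uniform one-sided frequency grid
#' from 0 Hz to the Nyquist frequency (factorization downstream needs
#' the full grid even when only a band is reported).
#'
#' @param epochs a [TrialEpochs-class] whose channels are the sites
#'   (e.g. the output of [bipolarDerive()]).
#' @param window analysis window in seconds (default 0 to 1 s).
#' @param nTapers number of Slepian tapers (default 15).
#' @param timeBandwidth DPSS time-bandwidth product; defaults to
#'   (nTapers + 1) / 2 so the requested taper count is admissible.
#' @param nfft FFT length (default: next power of two of the window).
#' @param channels optional channel subset.
#' @param trials optional trial mask (indices or logical).
#' @return a [CrossSpectralDensity-class].
#' @export
# Internal: per-site tapered Fourier coefficients, array
# [freq, taper, epoch, site]; the permutation test re-pairs epochs
# from these without recomputing any FFT.
taperedCoefs <- function(epochs, window, nTapers, timeBandwidth, nfft,
                         channels = NULL, trials = NULL) {
  dat <- epochs@data
  if (!is.null(trials)) dat <- dat[trials, , , drop = FALSE]
  if (!is.null(channels)) dat <- dat[, channels, , drop = FALSE]
  m <- dim(dat)[2]
  idx <- timesInWindow(epochs@times, window)
  if (!length(idx)) stop("analysis window outside the epoch")
  L <- length(idx)
  if (nTapers > 2 * timeBandwidth - 1)
    stop("nTapers must be <= 2 * timeBandwidth - 1")
  if (is.null(nfft)) nfft <- nextPow2(L)
  nf1 <- nfft %/% 2 + 1L
  tapers <- dpssTapers(L, timeBandwidth, nTapers)
  nt <- dim(dat)[1]
  coefs <- array(0i, c(nf1, nTapers, nt, m))
  pad <- matrix(0, nfft, m)
  for (tr in seq_len(nt)) {
    seg <- t(matrix(dat[tr, , idx], m, L))
    for (k in seq_len(nTapers)) {
      pad[] <- 0
      pad[seq_len(L), ] <- seg * tapers[, k]
      coefs[, k, tr, ] <- mvfft(pad)[seq_len(nf1), , drop = FALSE]
    }
  }
  sites <- if (!is.null(epochs@grid)) {
    tab <- channelTable(epochs@grid)
    if (!is.null(channels)) tab <- tab[match(channels, tab$channel), ]
    as.character(tab$channel)
  } else if (!is.null(channels)) as.character(channels)
  else as.character(seq_len(m))
  list(coefs = coefs, freqs = (0:(nfft %/% 2)) * epochs@fs / nfft,
       fs = epochs@fs, nTapers = as.integer(nTapers),
       nEpochs = as.integer(nt), window = window, sites = sites)
}

# Internal: taper- and epoch-averaged CSD array from cached
# coefficients, optionally with a per-site epoch permutation
# (columns of `perm` = sites).
csdFromCoefs <- function(co, perm = NULL) {
  d <- dim(co$coefs)
  nf1 <- d[1]; K <- d[2]; nt <- d[3]; m <- d[4]
  Fs <- vector("list", m)
  for (s in seq_len(m)) {
    sel <- if (is.null(perm)) seq_len(nt) else perm[, s]
    Fs[[s]] <- matrix(co$coefs[, , sel, s], nf1, K * nt)
  }
  csd <- array(0i, c(m, m, nf1))
  for (i in seq_len(m)) for (j in i:m) {
    v <- rowSums(Fs[[i]] * Conj(Fs[[j]])) / (K * nt)
    csd[i, j, ] <- v
    if (j > i) csd[j, i, ] <- Conj(v)
  }
  csd
}

#' Multitaper cross-spectral density of selected sites
#'
#' Taper- and epoch-averaged cross-periodograms of the site signals
#' within an analysis window, on the uniform one-sided frequency grid
#' from 0 Hz to the Nyquist frequency (factorization downstream needs
#' the full grid even when only a band is reported).
#'
#' @param epochs a [TrialEpochs-class] whose channels are the sites
#'   (e.g. the output of [bipolarDerive()]).
#' @param window analysis window in seconds (default 0 to 1 s).
#' @param nTapers number of Slepian tapers (default 15).
#' @param timeBandwidth DPSS time-bandwidth product; defaults to
#'   (nTapers + 1) / 2 so the requested taper count is admissible.
#' @param nfft FFT length (default: next power of two of the window).
#' @param channels optional channel subset.
#' @param trials optional trial mask (indices or logical).
#' @return a [CrossSpectralDensity-class].
#' @export
estimateCSD <- function(epochs, window = c(0, 1), nTapers = 15L,
                        timeBandwidth = (nTapers + 1) / 2, nfft = NULL,
                        channels = NULL, trials = NULL) {
  stopifnot(is(epochs, "TrialEpochs"))
  if (dim(epochs@data)[2] < 2 && is.null(channels))
    warning("fewer than 2 sites: only autospectra will be estimated")
  co <- taperedCoefs(epochs, window, nTapers, timeBandwidth, nfft,
                     channels, trials)
  if (co$nEpochs * co$nTapers < length(co$sites))
    warning("fewer taper-epoch averages than sites: cross-spectral matrices need not be positive semidefinite")
  new("CrossSpectralDensity", csd = csdFromCoefs(co), freqs = co$freqs,
      fs = co$fs, nTapers = co$nTapers, nEpochs = co$nEpochs,
      window = window, sites = co$sites)
}

#' Minimum-phase spectral matrix factorization (Wilson's algorithm)
#'
#' Factorizes a cross-spectral density S(f) = H(f) Sigma H(f)* into a
#' causal minimum-phase transfer function and an innovation covariance
#' by Wilson's iteration, initialized from the Cholesky factor of the
#' frequency-averaged CSD. Iteration stops when the relative change of
#' successive iterates falls below `tol` (default 1e-9) or after
#' `maxit` iterations, in which case the call fails with the residual.
#' Near-singular inputs are ridge-regularized and flagged.
#'
#' @param csd a [CrossSpectralDensity-class] on the full one-sided grid.
#' @param tol convergence tolerance on the successive-iterate change.
#' @param maxit iteration cap.
#' @return a [SpectralFactorization-class].
#' @export
wilsonFactorize <- function(csd, tol = 1e-9, maxit = 1000L) {
  stopifnot(is(csd, "CrossSpectralDensity"))
  core <- wilsonCore(csd@csd, fs = csd@fs, tol = tol, maxit = maxit)
  if (core$relerr > sqrt(tol))
    stop(sprintf("factorization did not converge in %d iterations (relative change %.2e)",
                 core$iterations, core$relerr))
  new("SpectralFactorization", H = core$H, Sigma = core$Sigma,
      freqs = csd@freqs, iterations = core$iterations,
      residual = core$residual)
}

#' Conditional Granger causality spectrum for one directed pair
#'
#' Geweke's frequency-resolved causality from `source` to `target`
#' conditional on the `conditioning` sites, from two nested
#' minimum-phase factorizations (with and without the source). With an
#' empty conditioning set this reduces to the pairwise measure.
#'
#' @param csd a [CrossSpectralDensity-class].
#' @param source,target site names or indices (distinct).
#' @param conditioning sites to condition on (default: all remaining
#'   sites in `csd`); must exclude source and target.
#' @param tol,maxit factorization controls, see [wilsonFactorize()].
#' @return data.frame with columns `freq` and `gc`.
#' @export
conditionalGC <- function(csd, source, target, conditioning = NULL,
                          tol = 1e-9, maxit = 1000L) {
  stopifnot(is(csd, "CrossSpectralDensity"))
  ix <- siteIndex(csd, source)
  jx <- siteIndex(csd, target)
  if (ix == jx) stop("source and target must differ")
  cx <- if (is.null(conditioning)) setdiff(seq_along(csd@sites), c(ix, jx))
        else vapply(conditioning, function(s) siteIndex(csd, s), integer(1))
  if (any(cx %in% c(ix, jx))) stop("conditioning set must exclude source and target")
  ord <- c(ix, jx, cx)
  sub <- csd@csd[ord, ord, , drop = FALSE]
  fullF <- wilsonCore(sub, fs = csd@fs, tol = tol, maxit = maxit)
  red <- sub[-1, -1, , drop = FALSE]
  redF <- wilsonCore(red, fs = csd@fs, tol = tol, maxit = maxit)
  data.frame(freq = csd@freqs,
             gc = gcFromFactorizations(fullF$H, fullF$Sigma, redF$H, redF$Sigma))
}

siteIndex <- function(csd, s) {
  if (is.numeric(s)) {
    s <- as.integer(s)
    if (s < 1 || s > length(csd@sites)) stop("site index out of range")
    return(s)
  }
  hit <- match(as.character(s), csd@sites)
  if (is.na(hit)) stop("unknown site: ", s)
  hit
}

#' Conditional GC spectra for all ordered site pairs
#'
#' Computes `gc[i, j, f]`, the influence of site i on site j at
#' frequency f, conditional on all remaining sites (or the marginal
#' pairwise measure with `conditional = FALSE`), restricted to a
#' reported frequency band of interest.
#'
#' @param csd a [CrossSpectralDensity-class].
#' @param conditional condition each pair on all remaining sites?
#' @param freqRange reported frequency range in Hz (default 0-150).
#' @param tol,maxit factorization controls.
#' @return a [GCSpectra-class].
#' @export
gcSpectra <- function(csd, conditional = TRUE, freqRange = c(0, 150),
                      tol = 1e-9, maxit = 1000L) {
  stopifnot(is(csd, "CrossSpectralDensity"))
  keep <- which(csd@freqs >= freqRange[1] & csd@freqs <= freqRange[2])
  gc <- gcFromCsdArray(csd@csd, fs = csd@fs, conditional = conditional,
                       keep = keep, tol = tol, maxit = maxit)
  new("GCSpectra", gc = gc, freqs = csd@freqs[keep], sites = csd@sites,
      threshold = matrix(numeric(0), 0, 0), p = matrix(numeric(0), 0, 0),
      padj = matrix(numeric(0), 0, 0), nPerm = 0L,
      diagnostics = list(conditional = conditional,
                         nTapers = csd@nTapers, nEpochs = csd@nEpochs))
}

# Internal: GC array for all ordered pairs from a raw one-sided CSD
# array. Shares the full factorization across pairs and, in the
# pairwise/bivariate case, the per-site scalar reduced factorizations.
gcFromCsdArray <- function(S, fs, conditional = TRUE,
                           keep = seq_len(dim(S)[3]), tol = 1e-9,
                           maxit = 1000L, scalarF = NULL) {
  m <- dim(S)[1]
  gc <- array(NA_real_, c(m, m, length(keep)))
  if (conditional && m > 2) {
    fullF <- wilsonCore(S, fs = fs, tol = tol, maxit = maxit)
    for (i in seq_len(m)) {
      others <- setdiff(seq_len(m), i)
      redF <- wilsonCore(S[others, others, , drop = FALSE],
                         fs = fs, tol = tol, maxit = maxit)
      for (j in others) {
        ordFull <- c(i, j, setdiff(others, j))
        ordRed <- match(c(j, setdiff(others, j)), others)
        spec <- gcFromFactorizations(
          fullF$H[ordFull, ordFull, , drop = FALSE],
          fullF$Sigma[ordFull, ordFull, drop = FALSE],
          redF$H[ordRed, ordRed, , drop = FALSE],
          redF$Sigma[ordRed, ordRed, drop = FALSE])
        gc[i, j, ] <- spec[keep]
      }
    }
  } else {
    if (is.null(scalarF))
      scalarF <- lapply(seq_len(m), function(s)
        wilsonCore(S[s, s, , drop = FALSE], fs = fs, tol = tol, maxit = maxit))
    for (i in seq_len(m - 1)) for (j in (i + 1):m) {
      sub <- S[c(i, j), c(i, j), , drop = FALSE]
      fullF <- wilsonCore(sub, fs = fs, tol = tol, maxit = maxit)
      gc[i, j, ] <- gcFromFactorizations(fullF$H, fullF$Sigma,
                                         scalarF[[j]]$H,
                                         scalarF[[j]]$Sigma)[keep]
      flip <- c(2L, 1L)
      gc[j, i, ] <- gcFromFactorizations(fullF$H[flip, flip, , drop = FALSE],
                                         fullF$Sigma[flip, flip],
                                         scalarF[[i]]$H,
                                         scalarF[[i]]$Sigma)[keep]
    }
  }
  gc
}

#' Permutation thresholds for conditional GC spectra
#'
#' Builds a null distribution by independently permuting the epoch
#' index of every site, which preserves each site's marginal spectrum
#' while destroying cross-site alignment. Per permutation and ordered
#' pair, the maximal GC value across the reported frequencies is
#' recorded; the per-pair significance threshold is the `percentile`
#' (default 99th) of these null maxima, and permutation p-values are
#' additionally Bonferroni-adjusted for `nTests` band-wise connections.
#'
#' @param epochs a [TrialEpochs-class] of site signals.
#' @param window,nTapers,timeBandwidth,nfft passed to [estimateCSD()].
#' @param nPerm number of permutations (default 1000; values below 100
#'   warn of an unstable null).
#' @param percentile quantile of the null maxima used as threshold.
#' @param nTests number of corrected band-wise connections (default 24:
#'   6 inter-subregional pairs x 4 bands).
#' @param freqRange reported frequency range (Hz).
#' @param conditional condition on remaining sites?
#' @param seed RNG seed for the permutations.
#' @return a [GCSpectra-class] with thresholds, p and adjusted p per
#'   ordered pair, and the null maxima in `diagnostics`.
#' @export
permutationThreshold <- function(epochs, window = c(0, 1), nTapers = 15L,
                                 timeBandwidth = (nTapers + 1) / 2,
                                 nfft = NULL, nPerm = 1000L,
                                 percentile = 0.99, nTests = 24L,
                                 freqRange = c(0, 150), conditional = TRUE,
                                 seed = NULL) {
  stopifnot(is(epochs, "TrialEpochs"))
  if (nPerm < 100) warning("nPerm < 100: permutation null will be unstable")
  if (nTrials(epochs) < 50)
    warning("fewer than ~50 epochs: permutation null may be unstable")
  co <- taperedCoefs(epochs, window, nTapers, timeBandwidth, nfft)
  keep <- which(co$freqs >= freqRange[1] & co$freqs <= freqRange[2])
  m <- length(co$sites)
  nt <- nTrials(epochs)
  obs <- new("GCSpectra",
             gc = gcFromCsdArray(csdFromCoefs(co), fs = co$fs,
                                 conditional = conditional, keep = keep),
             freqs = co$freqs[keep], sites = co$sites,
             threshold = matrix(numeric(0), 0, 0),
             p = matrix(numeric(0), 0, 0), padj = matrix(numeric(0), 0, 0),
             nPerm = 0L,
             diagnostics = list(conditional = conditional,
                                nTapers = co$nTapers, nEpochs = co$nEpochs))
  nullMax <- array(NA_real_, c(nPerm, m, m))
  # site-wise epoch shuffling leaves every marginal spectrum unchanged,
  # so the scalar reduced factorizations of the bivariate path can be
  # shared across permutations
  S0 <- csdFromCoefs(co)
  scalarF <- if (!conditional || m <= 2)
    lapply(seq_len(m), function(s) wilsonCore(S0[s, s, , drop = FALSE],
                                              fs = co$fs)) else NULL
  withSeed(seed, {
    for (b in seq_len(nPerm)) {
      perm <- vapply(seq_len(m), function(s) sample(nt), integer(nt))
      pgc <- gcFromCsdArray(csdFromCoefs(co, perm), fs = co$fs,
                            conditional = conditional, keep = keep,
                            scalarF = scalarF)
      nullMax[b, , ] <- apply(pgc, c(1, 2), max)
    }
  })
  thr <- apply(nullMax, c(2, 3), quantile, probs = percentile, na.rm = TRUE)
  obsMax <- apply(obs@gc, c(1, 2), max)
  p <- matrix(NA_real_, m, m)
  for (i in seq_len(m)) for (j in seq_len(m)) {
    if (i == j) next
    p[i, j] <- (1 + sum(nullMax[, i, j] >= obsMax[i, j])) / (nPerm + 1)
  }
  padj <- p
  padj[] <- pmin(1, p * nTests)
  new("GCSpectra", gc = obs@gc, freqs = obs@freqs, sites = obs@sites,
      threshold = thr, p = p, padj = padj, nPerm = as.integer(nPerm),
      diagnostics = c(obs@diagnostics,
                      list(nullMax = nullMax, percentile = percentile,
                           nTests = nTests)))
}

#' Frequency bands used for the GC directionality table
#'
#' Theta, alpha and beta follow the decoding band definitions; gamma is
#' taken as 31-70 Hz (the low-gamma decoding range) for consistency.
#'
#' @return named list of Hz intervals.
#' @export
gcBands <- function() {
  list(theta = c(5, 8), alpha = c(9, 13), beta = c(14, 30), gamma = c(31, 70))
}

# 3-bin moving-average smoothing used before peak detection.
smooth3 <- function(x) {
  n <- length(x)
  if (n < 3) return(x)
  y <- x
  y[2:(n - 1)] <- (x[1:(n - 2)] + x[2:(n - 1)] + x[3:n]) / 3
  y
}

#' Band-wise directionality statistic (dGC)
#'
#' For every unordered site pair and frequency band, decides which
#' direction dominates and quantifies the asymmetry: if the dominant
#' direction's (lightly smoothed) spectrum has a local peak inside the
#' band, dGC is the difference between the two directions at that peak
#' frequency; without a peak, dGC is the difference of band-averaged
#' values; if only one direction is significant, dGC is that
#' direction's band value; if neither is significant the band entry is
#' marked none.
#'
#' @param gc a [GCSpectra-class] with permutation thresholds (see
#'   [permutationThreshold()]).
#' @param bands named list of Hz intervals (default [gcBands()]).
#' @return data.frame with one row per unordered pair and band:
#'   `from`, `to` (the dominant direction, NA if none), `band`, `dgc`,
#'   `rule` ("peak", "average", "single", "tie" or "none"), and
#'   per-direction significance flags.
#' @export
dgcByBand <- function(gc, bands = gcBands()) {
  stopifnot(is(gc, "GCSpectra"))
  if (!length(gc@threshold))
    stop("dgcByBand needs permutation thresholds; run permutationThreshold() first")
  m <- length(gc@sites)
  rows <- list()
  for (i in seq_len(m - 1)) for (j in (i + 1):m) {
    for (bn in names(bands)) {
      bw <- bands[[bn]]
      bidx <- which(gc@freqs >= bw[1] & gc@freqs <= bw[2])
      if (!length(bidx)) next
      sij <- smooth3(gc@gc[i, j, ])[bidx]
      sji <- smooth3(gc@gc[j, i, ])[bidx]
      sigij <- any(gc@gc[i, j, bidx] > gc@threshold[i, j])
      sigji <- any(gc@gc[j, i, bidx] > gc@threshold[j, i])
      val <- function(s) {
        pk <- bandPeak(s)
        if (is.na(pk)) list(peak = NA_integer_, value = mean(s))
        else list(peak = pk, value = s[pk])
      }
      vij <- val(sij); vji <- val(sji)
      row <- data.frame(pair = paste(gc@sites[i], gc@sites[j], sep = "|"),
                        band = bn, from = NA_character_, to = NA_character_,
                        dgc = NA_real_, rule = "none",
                        sigForward = sigij, sigReverse = sigji,
                        stringsAsFactors = FALSE)
      if (sigij || sigji) {
        if (sigij && sigji) {
          if (isTRUE(all.equal(vij$value, vji$value))) {
            row$dgc <- 0; row$rule <- "tie"
          } else {
            dom <- if (vij$value >= vji$value) "ij" else "ji"
            dspec <- if (dom == "ij") sij else sji
            ospec <- if (dom == "ij") sji else sij
            dval <- if (dom == "ij") vij else vji
            if (!is.na(dval$peak)) {
              row$dgc <- dspec[dval$peak] - ospec[dval$peak]
              row$rule <- "peak"
            } else {
              row$dgc <- mean(dspec) - mean(ospec)
              row$rule <- "average"
            }
            row$from <- if (dom == "ij") gc@sites[i] else gc@sites[j]
            row$to <- if (dom == "ij") gc@sites[j] else gc@sites[i]
          }
        } else {
          dval <- if (sigij) vij else vji
          row$dgc <- dval$value
          row$rule <- "single"
          row$from <- if (sigij) gc@sites[i] else gc@sites[j]
          row$to <- if (sigij) gc@sites[j] else gc@sites[i]
        }
        if (!is.na(row$dgc)) row$dgc <- max(row$dgc, 0)
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  do.call(rbind, rows)
}

# Index of the highest interior local maximum (strictly above both
# neighbours) of a smoothed band spectrum, NA when no peak exists.
bandPeak <- function(s) {
  n <- length(s)
  if (n < 3) return(NA_integer_)
  cand <- which(s[2:(n - 1)] > s[1:(n - 2)] & s[2:(n - 1)] > s[3:n]) + 1L
  if (!length(cand)) return(NA_integer_)
  cand[which.max(s[cand])]
}

#' Classify site pairs by subregion and pool GC spectra
#'
#' Four sites carrying three subregion labels (one label doubled) form
#' C(4,2) = 6 site pairs: 5 inter-subregional and 1 intra-subregional.
#' GC spectra are averaged over site pairs sharing the doubled
#' subregion, yielding 6 directed subregion-level connections (3
#' subregion pairs x 2 directions).
#'
#' @param subregions character vector of subregion labels, one per
#'   site, in the site order of `gc` when given.
#' @param gc optional [GCSpectra-class] over the same sites to pool.
#' @return list with `sitePairs` (data.frame of the 6 site pairs and
#'   their type), `nInter`, `nIntra`, `subregions`, and when `gc` is
#'   supplied a pooled [GCSpectra-class] `pooled` over the 3 subregions.
#' @export
poolPairs <- function(subregions, gc = NULL) {
  n <- length(subregions)
  if (n != 4L) stop("exactly 4 sites are required")
  tab <- table(subregions)
  if (length(tab) != 3L || !all(sort(as.integer(tab)) == c(1L, 1L, 2L)))
    stop("labels must name 3 subregions with exactly one subregion doubled")
  pairs <- t(combn(n, 2))
  sitePairs <- data.frame(
    siteA = pairs[, 1], siteB = pairs[, 2],
    subA = subregions[pairs[, 1]], subB = subregions[pairs[, 2]],
    type = ifelse(subregions[pairs[, 1]] == subregions[pairs[, 2]],
                  "intra", "inter"),
    stringsAsFactors = FALSE)
  out <- list(sitePairs = sitePairs,
              nInter = sum(sitePairs$type == "inter"),
              nIntra = sum(sitePairs$type == "intra"),
              subregions = subregions)
  if (!is.null(gc)) {
    stopifnot(is(gc, "GCSpectra"),
              length(gc@sites) == n)
    subs <- sort(unique(subregions))
    ns <- length(subs)
    nf <- length(gc@freqs)
    pooledGC <- array(NA_real_, c(ns, ns, nf))
    pooledThr <- matrix(NA_real_, ns, ns)
    hasThr <- length(gc@threshold) > 0
    for (a in seq_len(ns)) for (b in seq_len(ns)) {
      if (a == b) next
      ia <- which(subregions == subs[a])
      ib <- which(subregions == subs[b])
      combos <- expand.grid(i = ia, j = ib)
      pooledGC[a, b, ] <- colMeans(
        t(vapply(seq_len(nrow(combos)),
                 function(r) gc@gc[combos$i[r], combos$j[r], ],
                 numeric(nf))), na.rm = TRUE)
      if (hasThr)
        pooledThr[a, b] <- mean(gc@threshold[cbind(combos$i, combos$j)])
    }
    out$pooled <- new("GCSpectra", gc = pooledGC, freqs = gc@freqs,
                      sites = subs,
                      threshold = if (hasThr) pooledThr else matrix(numeric(0), 0, 0),
                      p = matrix(numeric(0), 0, 0),
                      padj = matrix(numeric(0), 0, 0), nPerm = gc@nPerm,
                      diagnostics = list(pooledFrom = gc@sites,
                                         subregions = subregions))
  }
  out
}

#' @importFrom utils combn
NULL
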