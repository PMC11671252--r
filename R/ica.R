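# Independent component analysis of concatenated multichannel signals:
# square decomposition, topographic back-projection, permutation
# scoring of components by category decoding and subnetwork site
# selection.

#' Fit a square independent component decomposition
#'
#' Decomposes a channels x time matrix (or the concatenated trials of
#' a [TrialEpochs-class]) into as many maximally independent sources
#' as channels: after centering and whitening, a deterministic
#' symmetric fixed-point iteration maximizes negentropy with the
#' log-cosh contrast, which separates both sub- and super-Gaussian
#' sources. Component sign and scale are fixed by unit-norm
#' topographies with a positive maximal element, so reports are
#' reproducible.
#'
#' @param x a [TrialEpochs-class] or channels x time numeric matrix.
#' @param seed RNG seed for the orthonormal initialization.
#' @param maxit iteration cap (warns when reached without convergence;
#'   directions spanning a purely Gaussian subspace have no preferred
#'   rotation, so full convergence is not expected when many channels
#'   are plain noise).
#' @param tol convergence tolerance on the fixed-point update.
#' @return an [ICDecomposition-class].
#' @export
fitICA <- function(x, seed = NULL, maxit = 200L, tol = 1e-4) {
  if (is(x, "TrialEpochs")) {
    d <- dim(x@data)
    X <- matrix(aperm(x@data, c(2, 3, 1)), d[2], d[3] * d[1])
    fs <- x@fs; nTrials <- d[1]; times <- x@times; grid <- x@grid
  } else {
    X <- as.matrix(x)
    fs <- NA_real_; nTrials <- 1L; times = seq_len(ncol(X)); grid <- NULL
  }
  m <- nrow(X); n <- ncol(X)
  if (m > n) stop("more channels than time samples: decomposition underdetermined")
  mu <- rowMeans(X)
  Xc <- X - mu
  C <- tcrossprod(Xc) / (n - 1)
  e <- eigen(C, symmetric = TRUE)
  if (min(e$values) < 1e-10 * max(e$values))
    stop(sprintf("rank-deficient input (numerical rank %d of %d channels)",
                 sum(e$values > 1e-10 * max(e$values)), m))
  K <- diag(1 / sqrt(e$values)) %*% t(e$vectors)    # whitening, m x m
  Z <- K %*% Xc
  W <- withSeed(seed %||% 0L, {
    qr.Q(qr(matrix(rnorm(m * m), m, m)))
  })
  sym <- function(Wm) {
    s <- Wm %*% t(Wm)
    es <- eigen(s, symmetric = TRUE)
    es$vectors %*% diag(1 / sqrt(pmax(es$values, 1e-300))) %*%
      t(es$vectors) %*% Wm
  }
  W <- sym(W)
  converged <- FALSE
  it <- 0L
  for (it in seq_len(maxit)) {
    Y <- W %*% Z
    G <- tanh(Y)
    gDer <- rowMeans(1 - G^2)
    W1 <- sym(G %*% t(Z) / n - gDer * W)
    delta <- max(abs(abs(rowSums(W1 * W)) - 1))
    W <- W1
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning(sprintf("ICA did not converge in %d iterations", maxit))
  U <- W %*% K
  M <- solve(U)
  # sign/scale convention: unit-norm topography, positive max element
  for (j in seq_len(m)) {
    cnorm <- sqrt(sum(M[, j]^2))
    sgn <- sign(M[which.max(abs(M[, j])), j])
    cc <- cnorm * sgn
    M[, j] <- M[, j] / cc
    U[j, ] <- U[j, ] * cc
  }
  S <- U %*% Xc
  new("ICDecomposition", unmixing = U, mixing = M, sources = S,
      fs = fs, nTrials = as.integer(nTrials), times = times, grid = grid)
}

#' Topographic back-projection of one component
#'
#' The absolute values of the component's column of the mixing matrix
#' M = U^-1, i.e. each channel's contribution to the component,
#' mapped onto the electrode geometry when available.
#'
#' @param decomp an [ICDecomposition-class].
#' @param component component index.
#' @return data.frame with `channel`, `weight` and, when a grid is
#'   attached, `row`, `col`, `array`.
#' @export
icTopography <- function(decomp, component) {
  stopifnot(is(decomp, "ICDecomposition"))
  m <- ncol(decomp@mixing)
  if (component < 1 || component > m) stop("invalid component id")
  w <- abs(decomp@mixing[, component])
  if (!is.null(decomp@grid)) {
    tab <- channelTable(decomp@grid)
    data.frame(channel = tab$channel, row = tab$row, col = tab$col,
               array = tab$array, weight = w, stringsAsFactors = FALSE)
  } else {
    data.frame(channel = seq_along(w), weight = w)
  }
}

#' Re-epoch IC source activities on the trial structure
#'
#' @param decomp an [ICDecomposition-class] fitted from epochs.
#' @param labels per-trial labels to attach.
#' @return a [TrialEpochs-class] whose "channels" are components.
#' @export
sourceEpochs <- function(decomp, labels) {
  stopifnot(is(decomp, "ICDecomposition"))
  if (!is.finite(decomp@fs))
    stop("decomposition was not fitted from trial epochs")
  m <- nrow(decomp@sources); ns <- length(decomp@times)
  nt <- decomp@nTrials
  dat <- aperm(array(decomp@sources, c(m, ns, nt)), c(3, 1, 2))
  new("TrialEpochs", data = dat, fs = decomp@fs, times = decomp@times,
      labels = as.factor(labels), grid = NULL,
      provenance = "sourceEpochs()")
}

#' Score components by category decoding with a permutation null
#'
#' Each component's source activity is re-epoched and decomposed at
#' low resolution (default: 0.5 s window, 0.25 s step, the six probe
#' frequencies); the component's decoding value is the mean accuracy
#' over 300-2050 ms across those frequencies. Significance comes from
#' re-decoding under shuffled labels (the same shuffles for every
#' component), with Bonferroni adjustment across components by default.
#'
#' @param decomp an [ICDecomposition-class].
#' @param labels per-trial category labels.
#' @param nPerm permutations (0 = rank components without inference).
#' @param window scoring window in seconds (default 0.3-2.05 s).
#' @param freqList probe frequencies in Hz.
#' @param windowS,stepS,nTapers,timeBandwidth decomposition parameters.
#' @param nFolds folds per decoded point.
#' @param correction "bonferroni" (default) or "BH".
#' @param components optional subset of components to score.
#' @param seed RNG seed.
#' @return data.frame with `component`, decoding `value`, `p`, `padj`
#'   and `informative` (adjusted p < 0.05), ordered by component.
#' @export
scoreComponents <- function(decomp, labels, nPerm = 1000L,
                            window = c(0.3, 2.05),
                            freqList = c(3, 8, 12, 16, 58, 89),
                            windowS = 0.5, stepS = 0.25, nTapers = 6L,
                            timeBandwidth = 4, nFolds = 5L,
                            correction = c("bonferroni", "BH"),
                            components = NULL, seed = NULL) {
  correction <- match.arg(correction)
  eps <- sourceEpochs(decomp, labels)
  tfr <- multitaperTFR(eps, windowS, stepS, nTapers, timeBandwidth,
                       freqList = freqList)
  tidx <- timesInWindow(tfr@times, window, tol = 1 / eps@fs)
  if (!length(tidx)) stop("scoring window contains no decomposition time points")
  comps <- components %||% seq_len(nChannels(eps))
  labels <- droplevels(as.factor(labels))
  pts <- expand.grid(f = seq_along(tfr@freqs), w = tidx)
  valueOf <- function(comp, lab) {
    mean(vapply(seq_len(nrow(pts)), function(r) {
      feats <- matrix(tfr@power[, comp, pts$f[r], pts$w[r]], ncol = 1L)
      decodePoint(feats, lab, nFolds)$accuracy
    }, numeric(1)))
  }
  obs <- vapply(comps, valueOf, numeric(1), lab = labels)
  p <- rep(NA_real_, length(comps))
  if (nPerm > 0) {
    permVals <- withSeed(seed, {
      vapply(seq_len(nPerm), function(b) {
        shuffled <- sample(labels)
        vapply(comps, valueOf, numeric(1), lab = shuffled)
      }, numeric(length(comps)))
    })
    permVals <- matrix(permVals, nrow = length(comps))
    p <- vapply(seq_along(comps), function(i)
      (1 + sum(permVals[i, ] >= obs[i])) / (nPerm + 1), numeric(1))
  }
  padj <- if (all(is.na(p))) p
          else if (correction == "bonferroni") pmin(1, p * length(comps))
          else p.adjust(p, "BH")
  data.frame(component = comps, value = obs, p = p, padj = padj,
             informative = !is.na(padj) & padj < 0.05)
}

#' Select connectivity sites from a component topography
#'
#' Channels whose topographic weight exceeds the stated percentile of
#' all channels (both arrays jointly) are candidates; among them,
#' local maxima of the weight map (4-neighbourhood within an array)
#' are peaks, and the strongest `nSites` peaks are returned.
#'
#' @param topo data.frame from [icTopography()] including grid columns.
#' @param grid the [ElectrodeGrid-class] the topography lives on.
#' @param percentile percentile threshold (default 0.95).
#' @param nSites number of sites to select (default 4).
#' @return integer channel ids of the selected sites (fewer than
#'   `nSites` with a warning when not enough candidates exist).
#' @export
selectSites <- function(topo, grid, percentile = 0.95, nSites = 4L) {
  stopifnot(is(grid, "ElectrodeGrid"),
            all(c("channel", "weight") %in% names(topo)))
  w <- setNames(topo$weight, topo$channel)
  thr <- quantile(topo$weight, percentile, type = 7)
  above <- topo$channel[topo$weight > thr]
  if (!length(above)) {
    warning("no channel strictly exceeds the percentile (degenerate topography)")
    return(integer(0))
  }
  isPeak <- vapply(above, function(ch) {
    nb <- gridNeighbors(grid, ch)
    all(w[as.character(ch)] >= w[as.character(nb)])
  }, logical(1))
  peaks <- above[isPeak]
  if (!length(peaks)) peaks <- above
  peaks <- peaks[order(w[as.character(peaks)], decreasing = TRUE)]
  if (length(peaks) < nSites)
    warning(sprintf("only %d candidate sites above the %.0fth percentile",
                    length(peaks), 100 * percentile))
  head(peaks, nSites)
}

#' Amari separation index between an estimated unmixing and the truth
#'
#' Permutation- and scale-invariant distance between W A and a scaled
#' permutation matrix, normalized to `[0, 1]`; values near 0 indicate
#' successful source recovery.
#'
#' @param W estimated unmixing matrix (components x channels).
#' @param A true mixing matrix (channels x sources).
#' @return numeric scalar in `[0, 1]`.
#' @export
amariIndex <- function(W, A) {
  P <- abs(W %*% A)
  n <- nrow(P)
  r1 <- sum(rowSums(P / apply(P, 1, max)) - 1) / (n - 1)
  r2 <- sum(colSums(t(t(P) / apply(P, 2, max))) - 1) / (n - 1)
  (r1 + r2) / (2 * n)
}
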