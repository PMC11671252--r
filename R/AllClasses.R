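#' ElectrodeGrid: geometry and metadata of one or more electrode arrays
#'
#' Holds the channel table of a recording setup: for every channel its
#' (row, col) position within an array, the array it belongs to, a
#' surface/sulcal location flag and a free-text region label, together
#' with the inter-electrode pitch in millimetres. Rows are indexed
#' dorsal (row 1) to ventral; columns run along the long axis of the
#' array. Channel ids are row-major within each array and unique across
#' arrays.
#'
#' @slot channels data.frame with columns `channel`, `row`, `col`,
#'   `array`, `location`, `region`.
#' @slot pitch numeric, centre-to-centre electrode distance in mm.
#' @export
setClass("ElectrodeGrid",
  representation(channels = "data.frame", pitch = "numeric"))

setValidity("ElectrodeGrid", function(object) {
  ch <- object@channels
  need <- c("channel", "row", "col", "array", "location", "region")
  if (!all(need %in% names(ch)))
    return(paste("channel table must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(ch$channel)) return("channel ids must be unique")
  if (anyDuplicated(ch[, c("array", "row", "col")]))
    return("every (array, row, col) position must be unique")
  for (a in unique(ch$array)) {
    sub <- ch[ch$array == a, ]
    if (nrow(sub) != max(sub$row) * max(sub$col))
      return(sprintf("array '%s': rows x cols must equal its channel count", a))
  }
  if (length(object@pitch) != 1L || object@pitch <= 0)
    return("pitch must be a single positive number")
  TRUE
})

setClassUnion("ElectrodeGridOrNULL", c("ElectrodeGrid", "NULL"))

#' TrialEpochs: trial-epoched multichannel field potentials
#'
#' The universal exchange container between analysis stages: a
#' trials x channels x samples voltage array with its time axis
#' (seconds relative to stimulus onset), sampling rate, per-trial
#' category labels, electrode geometry and a processing log.
#'
#' @slot data numeric array, trials x channels x samples.
#' @slot fs sampling rate in Hz.
#' @slot times numeric vector of sample times (s), uniformly spaced at 1/fs.
#' @slot labels factor of per-trial category labels.
#' @slot grid [ElectrodeGrid-class] or NULL.
#' @slot provenance character vector, one entry per processing step.
#' @export
setClass("TrialEpochs",
  representation(data = "array", fs = "numeric", times = "numeric",
                 labels = "factor", grid = "ElectrodeGridOrNULL",
                 provenance = "character"))

setValidity("TrialEpochs", function(object) {
  d <- dim(object@data)
  if (length(d) != 3L) return("data must be a trials x channels x samples array")
  if (length(object@times) != d[3]) return("times length must equal sample count")
  if (length(object@times) > 1 && is.finite(object@fs)) {
    dt <- diff(object@times)
    if (isTRUE(max(abs(dt - 1 / object@fs)) > 1e-6 / object@fs))
      return("times must be uniformly spaced at 1/fs")
  }
  if (length(object@labels) != d[1]) return("labels length must equal trial count")
  if (!is.null(object@grid) && nrow(object@grid@channels) != d[2])
    return("grid channel count must match data channel dimension")
  TRUE
})

#' SpectralPerturbation: multitaper time-frequency power
#'
#' Raw (per-trial) or baseline-normalized (trial-averaged, dB)
#' time-frequency power. Raw power is a
#' trials x channels x frequencies x times array; normalized power is
#' channels x frequencies x times in dB relative to the pre-stimulus
#' baseline.
#'
#' @slot power numeric array (4-d raw, 3-d normalized).
#' @slot freqs frequency axis in Hz, strictly increasing.
#' @slot times window-centre times in seconds, strictly increasing.
#' @slot params list echoing the decomposition parameters.
#' @slot normalized logical flag.
#' @slot baselineWindow numeric(2) baseline window (s), or numeric(0).
#' @export
setClass("SpectralPerturbation",
  representation(power = "array", freqs = "numeric", times = "numeric",
                 params = "list", normalized = "logical",
                 baselineWindow = "numeric"))

setValidity("SpectralPerturbation", function(object) {
  d <- dim(object@power)
  nd <- length(d)
  if (!nd %in% c(3L, 4L)) return("power must be a 3-d or 4-d array")
  if (d[nd - 1] != length(object@freqs)) return("freqs length mismatch")
  if (d[nd] != length(object@times)) return("times length mismatch")
  if (is.unsorted(object@freqs, strictly = TRUE)) return("freqs must be strictly increasing")
  if (is.unsorted(object@times, strictly = TRUE)) return("times must be strictly increasing")
  if (!object@normalized && min(object@power) < 0) return("raw power must be nonnegative")
  TRUE
})

#' ICDecomposition: square independent component decomposition
#'
#' Stores the unmixing matrix U (components x channels), the mixing
#' matrix M = U^-1 (channels x components) whose columns are the
#' component topographies, and the continuous source activities
#' S(t) = U X(t) along with the trial structure needed to re-epoch
#' them.
#'
#' @slot unmixing components x channels matrix U.
#' @slot mixing channels x components matrix M = U^-1.
#' @slot sources components x time matrix of source activities.
#' @slot fs sampling rate in Hz.
#' @slot nTrials number of epochs concatenated into the sources.
#' @slot times per-epoch time axis (s).
#' @slot grid [ElectrodeGrid-class] or NULL, channel order reference.
#' @export
setClass("ICDecomposition",
  representation(unmixing = "matrix", mixing = "matrix", sources = "matrix",
                 fs = "numeric", nTrials = "integer", times = "numeric",
                 grid = "ElectrodeGridOrNULL"))

setValidity("ICDecomposition", function(object) {
  U <- object@unmixing; M <- object@mixing
  if (nrow(U) != ncol(U)) return("unmixing matrix must be square")
  if (!all(dim(M) == rev(dim(U))) || nrow(M) != nrow(U))
    return("mixing matrix must be the square inverse of unmixing")
  err <- max(abs(M %*% U - diag(nrow(U))))
  if (err > 1e-6) return(sprintf("M . U must equal identity (max deviation %.2e)", err))
  if (nrow(object@sources) != nrow(U)) return("one source row per component required")
  if (ncol(object@sources) != object@nTrials * length(object@times))
    return("source length must equal nTrials x samples per epoch")
  TRUE
})

#' CrossSpectralDensity: taper- and epoch-averaged cross-spectra
#'
#' Hermitian sites x sites cross-spectral matrices on a uniform
#' frequency grid from 0 Hz to the Nyquist frequency (the full grid is
#' retained because spectral factorization requires it; downstream
#' reporting is typically restricted to a band of interest).
#'
#' @slot csd complex array, sites x sites x frequencies.
#' @slot freqs one-sided frequency grid (Hz), 0 to fs/2.
#' @slot fs sampling rate (Hz).
#' @slot nTapers number of Slepian tapers used.
#' @slot nEpochs number of epochs averaged.
#' @slot window analysis window (s) within the epoch.
#' @slot sites character vector of site names.
#' @export
setClass("CrossSpectralDensity",
  representation(csd = "array", freqs = "numeric", fs = "numeric",
                 nTapers = "integer", nEpochs = "integer",
                 window = "numeric", sites = "character"))

setValidity("CrossSpectralDensity", function(object) {
  d <- dim(object@csd)
  if (length(d) != 3L || d[1] != d[2]) return("csd must be sites x sites x freqs")
  if (d[3] != length(object@freqs)) return("freqs length mismatch")
  if (d[1] != length(object@sites)) return("sites length mismatch")
  k <- min(3L, d[3])
  for (i in seq_len(k)) {
    S <- object@csd[, , i]
    if (max(abs(S - Conj(t(S)))) > 1e-8 * max(1, max(abs(S))))
      return("cross-spectral matrices must be Hermitian")
  }
  TRUE
})

#' SpectralFactorization: minimum-phase factorization of a CSD
#'
#' Result of Wilson's iterative spectral matrix factorization
#' S(f) = H(f) Sigma H(f)*, with the transfer function on the one-sided
#' frequency grid and the (frequency-independent) innovation covariance.
#'
#' @slot H complex array, sites x sites x frequencies.
#' @slot Sigma real innovation covariance, sites x sites.
#' @slot freqs one-sided frequency grid (Hz).
#' @slot iterations iterations used by the factorization.
#' @slot residual maximal relative reconstruction error over frequencies.
#' @export
setClass("SpectralFactorization",
  representation(H = "array", Sigma = "matrix", freqs = "numeric",
                 iterations = "integer", residual = "numeric"))

setValidity("SpectralFactorization", function(object) {
  d <- dim(object@H)
  if (length(d) != 3L || d[1] != d[2]) return("H must be sites x sites x freqs")
  if (d[3] != length(object@freqs)) return("freqs length mismatch")
  S <- object@Sigma
  if (max(abs(S - t(S))) > 1e-8 * max(1, max(abs(S))))
    return("Sigma must be symmetric")
  if (min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) <= 0)
    return("Sigma must be positive definite")
  TRUE
})

#' GCSpectra: frequency-resolved directed influence between sites
#'
#' Conditional (or pairwise) Granger causality spectra for every
#' ordered site pair, `gc[i, j, f]` holding the influence from site i
#' to site j at frequency f, optionally with permutation thresholds and
#' permutation p-values per ordered pair.
#'
#' @slot gc numeric array, sites x sites x frequencies (NA on the diagonal).
#' @slot freqs frequency axis (Hz).
#' @slot sites character site names.
#' @slot threshold per-pair permutation threshold matrix (or 0 x 0).
#' @slot p raw permutation p-value matrix (or 0 x 0).
#' @slot padj multiplicity-adjusted p-value matrix (or 0 x 0).
#' @slot nPerm number of permutations behind the thresholds.
#' @slot diagnostics list of estimation details.
#' @export
setClass("GCSpectra",
  representation(gc = "array", freqs = "numeric", sites = "character",
                 threshold = "matrix", p = "matrix", padj = "matrix",
                 nPerm = "integer", diagnostics = "list"))

setValidity("GCSpectra", function(object) {
  d <- dim(object@gc)
  if (length(d) != 3L || d[1] != d[2]) return("gc must be sites x sites x freqs")
  if (d[3] != length(object@freqs)) return("freqs length mismatch")
  if (d[1] != length(object@sites)) return("sites length mismatch")
  off <- object@gc
  for (i in seq_len(d[1])) off[i, i, ] <- 0
  if (min(off, na.rm = TRUE) < -1e-10) return("GC must be nonnegative")
  TRUE
})
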